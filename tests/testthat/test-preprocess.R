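test_that("antihypertensive adjustment adds 15 to SBP and 10 to DBP", {
  rec <- data.frame(value = c(130, 130), antihypertensive = c(TRUE, FALSE))
  out <- apply_medication_adjustment(rec, "sbp")
  expect_equal(out$value, c(145, 130))
  expect_equal(out$med_adjusted, c(TRUE, FALSE))
  out <- apply_medication_adjustment(data.frame(value = 80,
                                                antihypertensive = TRUE),
                                     "dbp")
  expect_equal(out$value, 90)
  # non-pressure traits are untouched even under medication
  out <- apply_medication_adjustment(data.frame(value = 70,
                                                antihypertensive = TRUE),
                                     "heart_rate")
  expect_equal(out$value, 70)
})

test_that("the four-part diabetes rule blanks glycemic traits", {
  g <- function(...) apply_exclusions(data.frame(...), "glucose")
  expect_true(is.na(g(value = 140, fasting = TRUE)$value))     # >= 126
  expect_equal(g(value = 125, fasting = TRUE)$value, 125)
  expect_true(is.na(g(value = 100, fasting = TRUE, hba1c = 6.5)$value))
  expect_equal(g(value = 100, fasting = TRUE, hba1c = 6.4)$value, 100)
  expect_true(is.na(g(value = 100, fasting = TRUE,
                      diabetes_dx = TRUE)$value))
  expect_true(is.na(g(value = 100, fasting = TRUE,
                      diabetes_meds = TRUE)$value))
  # glucose is additionally blanked when non-fasting
  out <- g(value = 100, fasting = FALSE)
  expect_true(is.na(out$value))
  expect_equal(out$excluded_reason, "non-fasting")
  # HbA1c at the inclusive boundary
  expect_true(is.na(apply_exclusions(data.frame(value = 6.5), "hba1c")$value))
  # HbA1c itself is not a fasting measure
  expect_equal(apply_exclusions(data.frame(value = 5.5, fasting = FALSE),
                                "hba1c")$value, 5.5)
})

test_that("lipid traits are blanked under lipid medication or non-fasting", {
  l <- function(...) apply_exclusions(data.frame(...), "total_cholesterol")
  expect_equal(l(value = 210, fasting = TRUE)$value, 210)
  expect_true(is.na(l(value = 210, lipid_lowering = TRUE)$value))
  expect_true(is.na(l(value = 210, fasting = FALSE)$value))
  expect_error(apply_exclusions(data.frame(value = 1), "unknown_trait"),
               "unknown phenotype")
})

test_that("residualization projects out sex, age, age^2 and site", {
  set.seed(8)
  n <- 300
  age <- runif(n, 50, 100)
  sex <- sample(c("male", "female"), n, TRUE)
  site <- sample(LETTERS[1:4], n, TRUE)
  y <- 2 * age + 0.01 * age^2 + (sex == "male") * 3 +
    c(A = 0, B = 1, C = -1, D = 2)[site] + rnorm(n)
  r <- residualize(y, sex, age, site)
  expect_lt(abs(cor(r, age)), 1e-10)
  expect_lt(abs(cor(r, age^2)), 1e-10)
  expect_lt(abs(mean(r[sex == "male"]) - mean(r[sex == "female"])), 1e-10)
  # constant phenotype gives all-zero residuals
  expect_equal(residualize(rep(5, n), sex, age, site), rep(0, n),
               tolerance = 1e-10)
  # a site level with < 2 observations is inestimable
  expect_error(residualize(y, sex, age, c("Z", site[-1])), "fewer than 2")
  # missing values stay missing
  y[3] <- NA
  expect_true(is.na(residualize(y, sex, age, site)[3]))
})

test_that("OLS slopes follow the days/365.25 rule", {
  rec <- data.frame(person_id = c("a", "a"), visit = 1:2,
                    visit_date = as.Date(c("2006-06-01", "2008-05-31")),
                    value = c(100, 110))
  out <- ols_slopes(rec)
  days <- as.numeric(as.Date("2008-05-31") - as.Date("2006-06-01"))
  expect_equal(out$years_between, days / 365.25)
  expect_equal(out$ols_slope, 10 / (days / 365.25))
  expect_equal(out$ols_slope, 5.0, tolerance = 0.005)
  # equal values give slope zero
  rec$value <- c(100, 100)
  expect_equal(ols_slopes(rec)$ols_slope, 0)
})

test_that("incomplete visit pairs yield missing slopes with reasons", {
  rec <- data.frame(person_id = c("a", "b", "b"), visit = c(1, 1, 2),
                    visit_date = as.Date(c("2006-06-01", "2006-06-01",
                                           "2015-01-01")),
                    value = c(100, 90, NA))
  out <- ols_slopes(rec)
  expect_true(all(is.na(out$ols_slope)))
  expect_equal(out$reason, c("incomplete pair", "incomplete pair"))
  bad <- data.frame(person_id = "a", visit = 1:2,
                    visit_date = as.Date(c("2008-01-01", "2006-01-01")),
                    value = c(1, 2))
  expect_error(ols_slopes(bad), "not after")
})
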