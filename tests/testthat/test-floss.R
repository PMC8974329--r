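test_that("exceptionality of deceased siblings is -log S at death age", {
  lt <- gomp_table()
  t_med <- survival_quantile(lt, "female", 1915, 0.5)
  expect_equal(sib_exceptionality(lt, "female", 1915, t_med, "dead"),
               -log(0.5), tolerance = 1e-8)
  t01 <- survival_quantile(lt, "female", 1915, 0.01)
  expect_equal(sib_exceptionality(lt, "female", 1915, t01, "dead"),
               -log(0.01), tolerance = 1e-8)
})

test_that("living siblings contribute -log S(t) + 1, matching quadrature", {
  lt <- gomp_table()
  t2 <- survival_quantile(lt, "female", 1915, exp(-2))  # -log S = 2
  expect_equal(sib_exceptionality(lt, "female", 1915, t2, "alive"), 3,
               tolerance = 1e-6)
  # quadrature oracle under the exact Gompertz law
  a <- 1e-4; b <- 0.085
  H <- function(t) (a / b) * (exp(b * t) - 1)
  Sf <- function(t) exp(-H(t))
  h <- function(t) a * exp(b * t)
  for (t0 in c(70, 85, 95)) {
    num <- integrate(function(u) H(u) * h(u) * Sf(u), t0, 200,
                     rel.tol = 1e-10)$value / Sf(t0)
    expect_equal(num, H(t0) + 1, tolerance = 1e-3)
    expect_equal(sib_exceptionality(lt, "female", 1915, t0, "alive"), num,
                 tolerance = 2e-3)
  }
  # alive at age 0: -log S(0) + 1 = 1
  expect_equal(sib_exceptionality(lt, "female", 1915, 0, "alive"), 1)
})

test_that("scoring errors identify unscoreable siblings", {
  lt <- gomp_table()
  expect_error(sib_exceptionality(lt, "female", 1915, NA, "dead"),
               "position: 1")
  expect_error(sib_exceptionality(lt, "female", 1915, 80, "unknown"),
               "vital_status")
  expect_error(floss_score(data.frame()[0, ], lt), "empty sibship")
})

test_that("a sibship with unit exceptionalities centers exactly to zero", {
  lt <- gomp_table()
  t1 <- survival_quantile(lt, "female", 1915, exp(-1))
  for (n in c(2, 5, 9)) {
    sibs <- data.frame(fid = "z", sex = "female", birth_year = 1915,
                       age_years = rep(t1, n), vital_status = "dead")
    sc <- floss_score(sibs, lt)
    expect_equal(sc$centered_component, 0, tolerance = 1e-8)
    expect_equal(sc$floss, 0, tolerance = 1e-8)
    expect_equal(sc$n_sibs, n)
  }
})

test_that("floss is monotone in any sibling's age at death and invariant to
           adding a unit-exceptionality sib", {
  lt <- gomp_table()
  ages <- seq(60, 100, by = 5)
  base <- data.frame(fid = "z", sex = "female", birth_year = 1915,
                     age_years = c(88, 92), vital_status = "dead")
  scores <- sapply(ages, function(a) {
    floss_score(rbind(base, data.frame(fid = "z", sex = "female",
                                       birth_year = 1915, age_years = a,
                                       vital_status = "dead")), lt)$floss
  })
  expect_true(all(diff(scores) >= 0))
  t1 <- survival_quantile(lt, "female", 1915, exp(-1))
  sc0 <- floss_score(base, lt)
  sc1 <- floss_score(rbind(base, data.frame(fid = "z", sex = "female",
                                            birth_year = 1915,
                                            age_years = t1,
                                            vital_status = "dead")), lt)
  expect_equal(sc1$centered_component, sc0$centered_component,
               tolerance = 1e-8)
})

test_that("centered component is size-invariant under table lifespans", {
  lt <- gomp_table()
  set.seed(31)
  mc <- function(n_sibs, reps) {
    replicate(reps, {
      age <- survival_quantile(lt, "female", 1915, runif(n_sibs))
      floss_score(data.frame(fid = "z", sex = "female", birth_year = 1915,
                             age_years = age, vital_status = "dead"),
                  lt)$centered_component
    })
  }
  a <- mc(3, 600); b <- mc(8, 600)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("sibs with unknown vital status are excluded but counted", {
  lt <- gomp_table()
  sibs <- data.frame(fid = "z", sex = "female", birth_year = 1915,
                     age_years = c(90, 85, NA),
                     vital_status = c("dead", "dead", NA))
  sc <- floss_score(sibs, lt)
  expect_equal(sc$n_sibs, 2)
  expect_equal(sc$n_excluded, 1)
})

test_that("eligibility applies the score threshold and family structure", {
  fam <- pedigree(data.frame(
    fid = "1", id = c("P", "S", "Sp", "O"),
    father = c(NA, NA, NA, "P"), mother = c(NA, NA, NA, "Sp"),
    sex = c(1, 2, 2, 1),
    generation = c("proband", "proband", "spouse-control", "offspring"),
    vital_status = c("alive", "alive", "alive", "alive"),
    age_years = c(95, 91, 90, 60), is_proband = c(TRUE, FALSE, FALSE, FALSE)))
  sc <- data.frame(floss = 7.0)
  expect_true(floss_eligible(fam, sc)$eligible)
  expect_equal(floss_eligible(fam, data.frame(floss = 6.99))$reasons,
               "score below threshold")
  fam2 <- fam; fam2$vital_status[2] <- "dead"
  el <- floss_eligible(fam2, data.frame(floss = 10))
  expect_false(el$eligible)
  expect_equal(el$reasons, "no living sibling")
  fam3 <- fam[fam$generation != "offspring", ]
  expect_equal(floss_eligible(fam3, data.frame(floss = 10))$reasons,
               "no offspring")
})
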