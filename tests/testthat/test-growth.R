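# simulate two-visit records on the age axis with known components
sim_growth <- function(n, s0 = 100, s1 = 0.04, s01 = 1, se = 15,
                       seed = 1, beta = c(0, 0)) {
  set.seed(seed)
  G <- matrix(c(s0, s01, s01, s1), 2)
  u <- matrix(rnorm(2 * n), n, 2) %*% chol(G + diag(1e-12, 2))
  a1 <- ifelse(runif(n) < 0.35, rnorm(n, 90.2, 6.6), rnorm(n, 61.2, 8.4))
  dt <- runif(n, 8, 10)
  c1 <- a1 - 75; c2 <- a1 + dt - 75
  int <- beta[1] + u[, 1]; slo <- beta[2] + u[, 2]
  list(df = data.frame(person_id = rep(seq_len(n), 2),
                       age = c(a1, a1 + dt), visit = rep(1:2, each = n),
                       value = c(int + slo * c1, int + slo * c2) +
                         rnorm(2 * n, 0, sqrt(se))),
       truth = data.frame(person_id = seq_len(n), intercept = int,
                          slope = slo),
       dt = dt)
}

test_that("noise-free line data is fit exactly with zero residual variance", {
  set.seed(4)
  n <- 80
  u <- cbind(rnorm(n, 0, 3), rnorm(n, 0, 0.3))
  a1 <- runif(n, 55, 95)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- c(a1[i], a1[i] + 5, a1[i] + 9)
    data.frame(person_id = i, age = ages, visit = 1:3,
               value = u[i, 1] + u[i, 2] * (ages - 75))
  }))
  f <- fit_growth_curve(df)
  expect_equal(f$sigma2_e, 0)
  m <- match(as.character(seq_len(n)), f$per_person$person_id)
  expect_equal(f$per_person$blup_slope[m], u[, 2], tolerance = 1e-6)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-9)
  expect_equal(fitted_measured_cor(f)[["visit1"]], 1.0, tolerance = 1e-9)
})

test_that("with no true slope variation BLUP slopes shrink to the mean", {
  sim <- sim_growth(400, s1 = 1e-12, s01 = 0, se = 15, seed = 6)
  f <- fit_growth_curve(sim$df)
  ols <- ols_slopes(data.frame(person_id = sim$df$person_id,
                               visit = sim$df$visit,
                               visit_date = as.Date("2006-01-01") +
                                 round((sim$df$age - 50) * 365.25),
                               value = sim$df$value))
  expect_lt(sd(f$per_person$blup_slope), 0.1 * sd(ols$ols_slope, na.rm = TRUE))
})

test_that("variance components are recovered on simulated cohorts", {
  rel <- t(sapply(1:5, function(s) {
    sim <- sim_growth(600, s0 = 1, s1 = 0.04, s01 = 0, se = 1, seed = s)
    f <- fit_growth_curve(sim$df)
    abs(c(f$G[1, 1], f$G[2, 2], f$sigma2_e) / c(1, 0.04, 1) - 1)
  }))
  expect_true(all(apply(rel, 2, median) < 0.25))
})

test_that("BLUP slopes beat OLS slopes in mean squared error when noise > 0", {
  for (s in 1:3) {
    sim <- sim_growth(500, seed = 10 + s)
    f <- fit_growth_curve(sim$df)
    m <- match(sim$truth$person_id, as.numeric(f$per_person$person_id))
    blup_mse <- mean((f$per_person$blup_slope[m] - sim$truth$slope)^2)
    v1 <- sim$df[sim$df$visit == 1, ]; v2 <- sim$df[sim$df$visit == 2, ]
    ols <- (v2$value - v1$value) / (v2$age - v1$age)
    ols_mse <- mean((ols - sim$truth$slope)^2)
    expect_lt(blup_mse, ols_mse)
  }
})

test_that("pure-noise data yields weak measured-fitted correlation", {
  set.seed(21)
  n <- 300
  a1 <- runif(n, 55, 95); dt <- runif(n, 8, 10)
  df <- data.frame(person_id = rep(seq_len(n), 2), age = c(a1, a1 + dt),
                   visit = rep(1:2, each = n), value = rnorm(2 * n))
  f <- fit_growth_curve(df)
  cc <- fitted_measured_cor(f)
  expect_true(all(cc < 0.5))
  expect_true(all(abs(cc) <= 1))
})

test_that("degenerate identical layouts are rejected as unidentifiable", {
  n <- 50
  df <- data.frame(person_id = rep(seq_len(n), 2),
                   time = rep(c(0, 9), each = n),
                   value = rnorm(2 * n))
  expect_error(fit_growth_curve(df), "identifiability")
})

test_that("fit object methods are coherent", {
  sim <- sim_growth(120, seed = 3)
  f <- fit_growth_curve(sim$df)
  expect_named(coef(f), c("intercept", "slope"))
  expect_equal(length(fitted(f)), nrow(f$data))
  expect_equal(fitted(f) + residuals(f), f$data$value)
  pr <- predict(f, data.frame(person_id = f$per_person$person_id[1:5],
                              time = 0))
  expect_equal(pr, f$per_person$blup_intercept[1:5])
  s <- simulate(f, nsim = 2, seed = 9)
  s2 <- simulate(f, nsim = 2, seed = 9)
  expect_equal(s, s2)
  expect_output(print(f), "Random-coefficient")
  expect_output(print(summary(f)), "covariance G")
  expect_true(abs(f$G[1, 2]) <= sqrt(f$G[1, 1] * f$G[2, 2]) + 1e-8)
})
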