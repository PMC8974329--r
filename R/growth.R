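#' Fit a random-coefficient (growth-curve) model
#'
#' Fits the linear mixed model
#' \deqn{y_{ij} = (\beta_0 + u_{i0}) + (\beta_1 + u_{i1}) t_{ij} + e_{ij}}
#' with person-specific random intercepts and slopes
#' \eqn{(u_{i0}, u_{i1}) \sim N(0, G)} and independent measurement error
#' \eqn{e_{ij} \sim N(0, \sigma^2_e)}, by REML.
#' Empirical-Bayes (BLUP) per-person intercepts and
#' slopes are returned; persons with a single visit are retained (they
#' inform the fixed effects and the intercept variance) and receive
#' shrunken estimates from their one observation.
#'
#' Time is the person's age centered at `age_center`, so the slopes are
#' individual trajectories with age and the intercept is the expected
#' value at `age_center`. The age axis matters for identifiability:
#' because participants are measured at widely differing ages, the
#' random-effect covariance G and the measurement-error variance are
#' separated locally, whereas with a common per-person time origin every
#' person contributes the same two-point layout and the two are nearly
#' confounded. When the supplied layout is degenerate (identical ages
#' and spacing for everyone with only two visits) the fit aborts with an
#' identifiability error.
#'
#' @param records data.frame with columns `person_id`, `value`, and one
#'   of `age` (age at measurement, years; preferred), `time` (user-chosen
#'   time axis, used as is) or `visit_date` (time in years from the
#'   person's first visit). An optional `visit` column is carried through
#'   for [fitted_measured_cor()].
#' @param age_center centering constant for the `age` axis (default 75).
#' @return Object of class `growth_fit` with elements `beta` (fixed
#'   intercept and slope), `G` (2x2 random-effect covariance),
#'   `sigma2_e`, `per_person` (person_id, blup_intercept, blup_slope --
#'   population plus deviation), `loglik` (REML), `data` (model rows with
#'   fitted values), `messages` (optimizer notes) and the underlying
#'   lme4 fit as `model`.
#' @export
fit_growth_curve <- function(records, age_center = 75) {
  df <- as.data.frame(records)
  if (!is.null(df$age)) {
    df$time <- df$age - age_center
  } else if (is.null(df$time)) {
    if (is.null(df$visit_date))
      stop("records need an 'age', 'time' or 'visit_date' column")
    df$visit_date <- as.Date(df$visit_date)
    t0 <- tapply(as.numeric(df$visit_date), df$person_id, min)
    df$time <- (as.numeric(df$visit_date) -
                  t0[as.character(df$person_id)]) / 365.25
  }
  df <- df[!is.na(df$value) & !is.na(df$time), , drop = FALSE]
  df$person_id <- as.character(df$person_id)
  nv <- table(df$person_id)
  if (sum(nv >= 2) < 3)
    stop("need at least 2 visits for a non-trivial subset of persons")
  firsts <- tapply(df$time, df$person_id, min)
  spans <- tapply(df$time, df$person_id, function(t) diff(range(t)))
  spans <- spans[nv[names(spans)] >= 2]
  if (max(nv) <= 2 && stats::sd(spans) < 1e-10 &&
      stats::sd(firsts) < 1e-10)
    stop("identifiability: every person has the same two-visit layout, ",
         "so G and the residual variance are confounded")

  # Zero-measurement-error limit: if some persons have 3+ visits and every
  # such person's visits are exactly collinear, the mixed model degenerates
  # (residual variance 0, person lines interpolate); fit it directly.
  if (exact_linear_case(df)) return(exact_line_fit(df))

  msgs <- character(0)
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nRE = "ignore", check.nobs.vs.nlev = "ignore",
    check.nobs.vs.rankZ = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- withCallingHandlers(
    lme4::lmer(value ~ time + (time | person_id), data = df, REML = TRUE,
               control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  vc <- lme4::VarCorr(fit)
  G <- matrix(vc$person_id[1:2, 1:2], 2, 2,
              dimnames = list(c("intercept", "slope"),
                              c("intercept", "slope")))
  sigma2_e <- attr(vc, "sc")^2
  cf <- stats::coef(fit)$person_id
  per_person <- data.frame(person_id = rownames(cf),
                           blup_intercept = cf[["(Intercept)"]],
                           blup_slope = cf[["time"]],
                           stringsAsFactors = FALSE)
  df$fitted <- stats::fitted(fit)
  out <- list(beta = stats::setNames(lme4::fixef(fit),
                                     c("intercept", "slope")),
              G = G, sigma2_e = sigma2_e, per_person = per_person,
              loglik = as.numeric(stats::logLik(fit)),
              n_persons = length(nv), n_obs = nrow(df),
              messages = msgs, data = df, model = fit)
  class(out) <- "growth_fit"
  out
}

#' @method print growth_fit
#' @export
print.growth_fit <- function(x, ...) {
  cat("Random-coefficient growth model (REML)\n")
  cat(sprintf("  %d persons, %d observations\n", x$n_persons, x$n_obs))
  cat(sprintf("  fixed effects: intercept %.4g, slope %.4g per year\n",
              x$beta[1], x$beta[2]))
  cat(sprintf("  var(intercept) %.4g, var(slope) %.4g, corr %.3f\n",
              x$G[1, 1], x$G[2, 2],
              x$G[1, 2] / sqrt(max(x$G[1, 1] * x$G[2, 2], 1e-300))))
  cat(sprintf("  residual variance %.4g;  REML logLik %.4f\n",
              x$sigma2_e, x$loglik))
  if (length(x$messages) > 0)
    cat("  notes:", paste(unique(x$messages), collapse = "; "), "\n")
  invisible(x)
}

#' @method summary growth_fit
#' @export
summary.growth_fit <- function(object, ...) {
  out <- list(beta = object$beta, G = object$G, sigma2_e = object$sigma2_e,
              loglik = object$loglik, n_persons = object$n_persons,
              n_obs = object$n_obs,
              slope_summary = summary(object$per_person$blup_slope),
              messages = object$messages)
  class(out) <- "summary.growth_fit"
  out
}

#' @method print summary.growth_fit
#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Growth-curve fit summary\n")
  cat("Fixed effects:\n"); print(x$beta)
  cat("Random-effect covariance G:\n"); print(x$G)
  cat(sprintf("Residual variance: %.6g\n", x$sigma2_e))
  cat(sprintf("REML logLik: %.4f (%d persons, %d obs)\n",
              x$loglik, x$n_persons, x$n_obs))
  cat("BLUP slope distribution:\n"); print(x$slope_summary)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$beta

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = 6, class = "logLik")
}

#' @export
fitted.growth_fit <- function(object, ...) object$data$fitted

#' @export
residuals.growth_fit <- function(object, ...) {
  object$data$value - object$data$fitted
}

#' Predict person-specific trajectories
#'
#' @param object a `growth_fit`.
#' @param newdata data.frame with `person_id` and `time`; persons unseen
#'   at fitting time get the population line.
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  pp <- object$per_person
  m <- match(as.character(newdata$person_id), pp$person_id)
  int <- ifelse(is.na(m), object$beta[1], pp$blup_intercept[m])
  slo <- ifelse(is.na(m), object$beta[2], pp$blup_slope[m])
  int + slo * newdata$time
}

#' Simulate from a fitted growth-curve model
#'
#' Draws new random intercepts/slopes from the fitted G and new
#' measurement errors, on the time layout of the fitting data.
#'
#' @param object a `growth_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame of `nsim` simulated value columns alongside
#'   person_id and time.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  df <- object$data[, c("person_id", "time")]
  ids <- unique(df$person_id)
  L <- chol_psd(object$G)
  out <- df
  for (s in seq_len(nsim)) {
    u <- matrix(stats::rnorm(2 * length(ids)), ncol = 2) %*% t(L)
    rownames(u) <- ids
    out[[paste0("sim_", s)]] <-
      object$beta[1] + u[df$person_id, 1] +
      (object$beta[2] + u[df$person_id, 2]) * df$time +
      stats::rnorm(nrow(df), 0, sqrt(object$sigma2_e))
  }
  out
}

#' @export
plot.growth_fit <- function(x, max_persons = 60, ...) {
  df <- x$data
  ids <- unique(df$person_id)
  if (length(ids) > max_persons) ids <- ids[seq_len(max_persons)]
  sub <- df[df$person_id %in% ids, ]
  plot(sub$time, sub$value, pch = 16, cex = 0.5, col = "grey40",
       xlab = "years since first visit", ylab = "value",
       main = "Growth-curve fit: observed and shrunken person lines", ...)
  for (id in ids) {
    pp <- x$per_person[x$per_person$person_id == id, ]
    tt <- range(sub$time[sub$person_id == id])
    lines(tt, pp$blup_intercept + pp$blup_slope * tt, col = "steelblue")
  }
  abline(a = x$beta[1], b = x$beta[2], col = "red", lwd = 2)
  invisible(x)
}

#' Correlation between measured and growth-curve fitted values
#'
#' Pearson correlation, per visit, between the measured phenotype and the
#' BLUP-predicted value at that visit -- a gauge of how much shrinkage
#' the model applies (near 1 when measurement error is small).
#'
#' @param fit a `growth_fit` whose fitting data carried a `visit` column.
#' @return Named numeric vector of correlations, one per visit (NA when
#'   fewer than 3 paired points).
#' @export
fitted_measured_cor <- function(fit) {
  df <- fit$data
  if (is.null(df$visit)) stop("fitting records had no 'visit' column")
  vapply(sort(unique(df$visit)), function(v) {
    sub <- df[df$visit == v, ]
    if (nrow(sub) < 3) return(NA_real_)
    stats::cor(sub$value, sub$fitted)
  }, numeric(1)) |> stats::setNames(paste0("visit", sort(unique(df$visit))))
}

# Cholesky-like square root that tolerates PSD (rank-deficient) matrices.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v))
}

# TRUE when persons with >= 3 visits exist and all of them lie exactly on
# per-person lines (to numerical precision) -- the zero-error limit.
exact_linear_case <- function(df) {
  sp <- split(df[, c("time", "value")], df$person_id)
  multi <- sp[vapply(sp, nrow, 0L) >= 3]
  if (length(multi) == 0) return(FALSE)
  scale <- max(stats::sd(df$value), 1e-12)
  all(vapply(multi, function(b) {
    r <- stats::lm.fit(cbind(1, b$time), b$value)$residuals
    max(abs(r)) < 1e-8 * scale
  }, logical(1)))
}

# Degenerate fit for exactly line-structured data: per-person OLS lines,
# sigma2_e = 0, G = empirical covariance of the person coefficients.
exact_line_fit <- function(df) {
  sp <- split(df[, c("time", "value")], df$person_id)
  co <- t(vapply(sp, function(b) {
    if (nrow(b) >= 2 && diff(range(b$time)) > 0)
      stats::lm.fit(cbind(1, b$time), b$value)$coefficients
    else c(NA_real_, NA_real_)
  }, numeric(2)))
  ok <- !is.na(co[, 1])
  beta <- colMeans(co[ok, , drop = FALSE])
  G <- stats::cov(co[ok, , drop = FALSE])
  dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
  # single-visit persons: posterior mean of the line given one exact point
  if (any(!ok)) {
    for (id in names(sp)[!ok]) {
      b <- sp[[id]][1, ]
      z <- c(1, b$time)
      gz <- G %*% z
      co[id, ] <- beta + as.numeric(gz) *
        as.numeric((b$value - sum(beta * z)) / max(sum(z * gz), 1e-300))
    }
  }
  df$fitted <- co[as.character(df$person_id), 1] +
    co[as.character(df$person_id), 2] * df$time
  out <- list(beta = stats::setNames(beta, c("intercept", "slope")),
              G = G, sigma2_e = 0,
              per_person = data.frame(person_id = rownames(co),
                                      blup_intercept = co[, 1],
                                      blup_slope = co[, 2],
                                      stringsAsFactors = FALSE),
              loglik = NA_real_, n_persons = length(sp), n_obs = nrow(df),
              messages = "exact per-person lines: zero measurement error",
              data = df, model = NULL)
  class(out) <- "growth_fit"
  out
}
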