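#' Life table object
#'
#' A life table stores the survival function S(age) on an integer age grid
#' for strata defined by sex and a birth-cohort range. Within each stratum
#' S(0) = 1, S is non-increasing and lies in [0, 1].
#'
#' @param df data.frame with columns `sex` ("male"/"female"), `cohort_start`,
#'   `cohort_end` (birth years delimiting the stratum), `age` (integer
#'   years, strictly increasing within stratum, starting at 0) and
#'   `survival`.
#' @return An object of class `lifetable`.
#' @export
lifetable <- function(df) {
  req <- c("sex", "cohort_start", "cohort_end", "age", "survival")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("lifetable is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sex <- decode_sex(df$sex)
  key <- paste(df$sex, df$cohort_start, df$cohort_end)
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$age), , drop = FALSE]
    if (any(diff(sub$age) <= 0))
      stop("stratum ", k, ": age grid not strictly increasing")
    if (sub$age[1] != 0 || abs(sub$survival[1] - 1) > 1e-12)
      stop("stratum ", k, ": table must start at age 0 with S(0) = 1")
    if (any(sub$survival < 0 | sub$survival > 1))
      stop("stratum ", k, ": survival outside [0, 1]")
    if (any(diff(sub$survival) > 1e-12))
      stop("stratum ", k, ": survival must be non-increasing in age")
  }
  df <- df[order(df$sex, df$cohort_start, df$age), ]
  rownames(df) <- NULL
  class(df) <- c("lifetable", "data.frame")
  df
}

#' Read / write a life-table CSV
#'
#' CSV columns: sex, cohort_start, cohort_end, age, survival.
#'
#' @param path file path.
#' @return [lifetable()] object (for `read_lifetable`).
#' @export
read_lifetable <- function(path) {
  lifetable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_lifetable
#' @param table a [lifetable()].
#' @export
write_lifetable <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

resolve_stratum <- function(table, sex, birth_year) {
  sex <- decode_sex(sex)
  sub <- table[table$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no life-table stratum for sex = ", sex)
  inside <- birth_year >= sub$cohort_start & birth_year <= sub$cohort_end
  if (any(inside)) return(sub[inside, , drop = FALSE])
  # nearest stratum when the birth year falls outside every cohort range
  grp <- paste(sub$cohort_start, sub$cohort_end)
  ug <- unique(grp)
  mids <- vapply(ug, function(g) {
    r <- sub[grp == g, ][1, ]
    (r$cohort_start + r$cohort_end) / 2
  }, numeric(1))
  best <- ug[which.min(abs(mids - birth_year))]
  warning("birth year ", birth_year, " outside all cohort ranges for sex ",
          sex, "; using nearest stratum ", best)
  sub[grp == best, , drop = FALSE]
}

# Gompertz tail parameters (a, b) fitted through the last two grid points
# of a cumulative-hazard curve; falls back to a constant-hazard
# (exponential) tail when the hazard is not accelerating.
fit_gompertz_tail <- function(t1, H1, t2, H2) {
  if (H1 <= 0) return(list(type = "exp", h = (H2 - H1) / (t2 - t1), t2 = t2, H2 = H2))
  r <- H2 / H1
  f <- function(b) (exp(b * t2) - 1) / (exp(b * t1) - 1) - r
  if (f(1e-8) >= 0) {  # ratio <= t2/t1: hazard not accelerating
    return(list(type = "exp", h = (H2 - H1) / (t2 - t1), t2 = t2, H2 = H2))
  }
  b <- tryCatch(stats::uniroot(f, c(1e-8, 2), tol = 1e-12)$root,
                error = function(e) NA_real_)
  if (is.na(b))
    return(list(type = "exp", h = (H2 - H1) / (t2 - t1), t2 = t2, H2 = H2))
  a <- H2 * b / (exp(b * t2) - 1)
  list(type = "gompertz", a = a, b = b)
}

#' Evaluate a life-table survival probability
#'
#' Linear interpolation of log S between grid ages (piecewise-constant
#' hazard within a year, the standard actuarial convention); beyond the
#' last grid age the cumulative hazard is extrapolated with a Gompertz
#' tail fitted to the last two grid points (constant-hazard fallback if
#' the tabulated hazard is not accelerating). The result is clamped to
#' (1e-12, 1].
#'
#' @param table a [lifetable()].
#' @param sex "male"/"female" (1/2 accepted).
#' @param birth_year birth year used to resolve the cohort stratum.
#' @param age age in years (vectorised), must be >= 0.
#' @return Survival probabilities S(age).
#' @export
survival_prob <- function(table, sex, birth_year, age) {
  stopifnot(inherits(table, "lifetable"))
  if (any(age < 0)) stop("age must be non-negative")
  sub <- resolve_stratum(table, sex, birth_year)
  sub <- sub[order(sub$age), , drop = FALSE]
  H <- -log(pmax(sub$survival, 1e-300))
  out <- numeric(length(age))
  last <- nrow(sub)
  inb <- age <= sub$age[last]
  if (any(inb))
    out[inb] <- stats::approx(sub$age, H, xout = age[inb], rule = 2)$y
  if (any(!inb)) {
    tail <- fit_gompertz_tail(sub$age[last - 1], H[last - 1],
                              sub$age[last], H[last])
    extra <- age[!inb]
    out[!inb] <- if (tail$type == "gompertz") {
      tail$a / tail$b * (exp(tail$b * extra) - 1)
    } else {
      tail$H2 + tail$h * (extra - tail$t2)
    }
  }
  pmin(pmax(exp(-out), 1e-12), 1)
}

#' Inverse survival: age at which S(age) = u
#'
#' Exact inverse of the interpolated/extrapolated survival curve used by
#' [survival_prob()], so that lifespans drawn by inverse transform are
#' distributed according to the table.
#'
#' @inheritParams survival_prob
#' @param u survival probabilities in (0, 1] (vectorised).
#' @return Ages T with S(T) = u.
#' @export
survival_quantile <- function(table, sex, birth_year, u) {
  stopifnot(inherits(table, "lifetable"))
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  sub <- resolve_stratum(table, sex, birth_year)
  sub <- sub[order(sub$age), , drop = FALSE]
  H <- -log(pmax(sub$survival, 1e-300))
  Hq <- -log(u)
  out <- numeric(length(u))
  last <- nrow(sub)
  inb <- Hq <= H[last]
  if (any(inb)) {
    # H is non-decreasing in age; invert by interpolation on unique H values
    keep <- !duplicated(H)
    out[inb] <- stats::approx(H[keep], sub$age[keep], xout = Hq[inb],
                              rule = 2)$y
  }
  if (any(!inb)) {
    tail <- fit_gompertz_tail(sub$age[last - 1], H[last - 1],
                              sub$age[last], H[last])
    Hx <- Hq[!inb]
    out[!inb] <- if (tail$type == "gompertz") {
      log(Hx * tail$b / tail$a + 1) / tail$b
    } else {
      tail$t2 + (Hx - tail$H2) / tail$h
    }
  }
  out
}

#' Synthesize a Gompertz life table
#'
#' Tabulates S(t) = exp(-(a/b) (exp(b t) - 1)) at integer ages
#' 0..max_age for one sex/cohort stratum.
#'
#' @param a baseline hazard (> 0).
#' @param b hazard slope per year (> 0).
#' @param sex stratum sex.
#' @param cohort_start,cohort_end birth-cohort range of the stratum.
#' @param max_age last tabulated age (>= 1).
#' @return A [lifetable()] with one stratum.
#' @export
make_gompertz_table <- function(a, b, sex = "female", cohort_start = 1900,
                                cohort_end = 1930, max_age = 110) {
  if (a <= 0 || b <= 0) stop("Gompertz parameters a and b must be positive")
  if (max_age < 1) stop("max_age must be at least 1")
  ages <- 0:max_age
  lifetable(data.frame(sex = sex, cohort_start = cohort_start,
                       cohort_end = cohort_end, age = ages,
                       survival = exp(-(a / b) * (exp(b * ages) - 1))))
}

#' Two-sex Gompertz life table
#'
#' Convenience wrapper building one stratum per sex from per-sex Gompertz
#' parameters.
#'
#' @param a named vector `c(male =, female =)` of baseline hazards.
#' @param b named vector of hazard slopes (recycled if length 1).
#' @inheritParams make_gompertz_table
#' @export
make_gompertz_table2 <- function(a = c(male = 1.1e-4, female = 6e-5),
                                 b = c(male = 0.085, female = 0.085),
                                 cohort_start = 1900, cohort_end = 1930,
                                 max_age = 110) {
  if (length(b) == 1) b <- stats::setNames(rep(b, 2), c("male", "female"))
  parts <- lapply(c("male", "female"), function(s)
    as.data.frame(make_gompertz_table(a[[s]], b[[s]], sex = s,
                                      cohort_start = cohort_start,
                                      cohort_end = cohort_end,
                                      max_age = max_age)))
  lifetable(do.call(rbind, parts))
}
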