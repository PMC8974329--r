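# Internal: per-family eigendecomposition of the additive relationship
# matrix A = 2*Phi restricted to the ids carrying phenotype values.
# Because cross-family kinship is 0, A is block diagonal and each block
# can be decomposed separately; the REML likelihood then reduces to
# weighted sums over the concatenated eigenpairs.
relationship_eigen <- function(kin, ids) {
  m <- match(ids, kin$ids)
  if (anyNA(m))
    stop("phenotype ids missing from kinship matrix: ",
         paste(ids[is.na(m)], collapse = ", "))
  fids <- kin$fids[m]
  d <- numeric(0); z_rows <- list(); k <- 0L
  U <- vector("list", 0)
  ord <- integer(0)
  for (fam in unique(fids)) {
    sel <- which(fids == fam)
    A <- 2 * kin$phi[m[sel], m[sel], drop = FALSE]
    e <- eigen(A, symmetric = TRUE)
    d <- c(d, pmax(e$values, 1e-10))
    U[[length(U) + 1L]] <- e$vectors
    ord <- c(ord, sel)
    k <- k + length(sel)
  }
  list(d = d, U = U, ord = ord, fids = fids)
}

# Rotate a vector into the eigenbasis (per family block).
rotate_eigen <- function(ed, x) {
  out <- numeric(length(x))
  pos <- 1L
  for (U in ed$U) {
    nb <- ncol(U)
    idx <- ed$ord[pos:(pos + nb - 1L)]
    out[pos:(pos + nb - 1L)] <- crossprod(U, x[idx])
    pos <- pos + nb
  }
  out
}

# REML log-likelihood of y ~ N(1*mu, sigma2*(h2*A + (1-h2)*I)) at a given
# h2, with mu and sigma2 profiled out. Works on the rotated data.
reml_loglik_h2 <- function(h2, d, z, w, n) {
  v <- h2 * d + (1 - h2)
  C <- sum(w^2 / v)
  mu <- sum(w * z / v) / C
  rss <- sum((z - mu * w)^2 / v)
  s2 <- rss / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) + sum(log(v)) + log(C))
}

#' Polygenic REML heritability under the kinship model
#'
#' Estimates the additive polygenic model
#' \deqn{y \sim N(\mu 1,\; 2\Phi\,\sigma^2_g + I\,\sigma^2_e)}
#' by REML, where \eqn{\Phi} is the pedigree kinship matrix. Covariate
#' effects are assumed already removed (two-stage workflow: adjust, then
#' estimate). The likelihood is profiled over the grand mean and the
#' total variance, leaving a one-dimensional search over
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e) \in [0, 1]};
#' the eigendecomposition of \eqn{2\Phi} (block-wise per family) makes
#' each likelihood evaluation a weighted sum. A boundary estimate is
#' reported as exactly 0 or 1, and the likelihood-ratio test against
#' \eqn{\sigma^2_g = 0} uses the half-and-half chi-square boundary
#' mixture.
#'
#' @param values named numeric vector of person-level phenotype values
#'   (names are pedigree ids); NAs dropped.
#' @param kin a [kinship()] matrix covering the ids.
#' @param trait_name label carried into the result.
#' @return Object of class `polygenic_fit` with fields `trait_name`,
#'   `n_used`, `sigma2_g`, `sigma2_e`, `h2`, `se_h2`, `loglik`, `lrt`,
#'   `lrt_p`, `mu`.
#' @export
polygenic_reml <- function(values, kin, trait_name = "trait") {
  stopifnot(inherits(kin, "kinship_matrix"))
  values <- values[!is.na(values)]
  ids <- names(values)
  if (is.null(ids)) stop("values must be a named vector of person ids")
  n <- length(values)
  if (n < 30) stop("need phenotype values for at least 30 individuals")
  m <- match(ids, kin$ids)
  if (anyNA(m))
    stop("phenotype ids missing from kinship matrix: ",
         paste(ids[is.na(m)], collapse = ", "))
  if (length(unique(kin$fids[m])) < 2)
    stop("need individuals from at least 2 families")
  A <- 2 * kin$phi[m, m, drop = FALSE]
  if (max(abs(A - diag(n))) < 1e-8)
    stop("identifiability: all individuals mutually unrelated, ",
         "sigma2_g and sigma2_e are confounded")

  ed <- relationship_eigen(kin, ids)
  y <- as.numeric(values)
  z <- rotate_eigen(ed, y)
  w <- rotate_eigen(ed, rep(1, n))
  ll <- function(h2) reml_loglik_h2(h2, ed$d, z, w, n)

  grid <- seq(0, 1, length.out = 51)
  lg <- vapply(grid, ll, numeric(1))
  best <- grid[which.max(lg)]
  lo <- max(0, best - 0.04); hi <- min(1, best + 0.04)
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  cll <- vapply(cand, ll, numeric(1))
  h2 <- cand[which.max(cll)]
  llmax <- max(cll)
  if (h2 < 1e-6) h2 <- 0
  if (h2 > 1 - 1e-6) h2 <- 1

  v <- h2 * ed$d + (1 - h2)
  C <- sum(w^2 / v)
  mu <- sum(w * z / v) / C
  s2 <- sum((z - mu * w)^2 / v) / (n - 1)

  ll0 <- ll(0)
  lrt <- max(0, 2 * (llmax - ll0))
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                    lower.tail = FALSE)
  se_h2 <- NA_real_
  if (h2 > 1e-4 && h2 < 1 - 1e-4) {
    eps <- 1e-4
    d2 <- (ll(h2 + eps) - 2 * llmax + ll(h2 - eps)) / eps^2
    if (is.finite(d2) && d2 < 0) se_h2 <- sqrt(-1 / d2)
  }
  out <- list(trait_name = trait_name, n_used = n,
              sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2,
              h2 = h2, se_h2 = se_h2, loglik = llmax,
              lrt = lrt, lrt_p = lrt_p, mu = mu)
  class(out) <- "polygenic_fit"
  out
}

#' REML profile over heritability
#'
#' Brute-force profile of the REML log-likelihood over a grid of
#' \eqn{h^2} values (total variance and mean profiled out at each point).
#' Used as the grid oracle for [polygenic_reml()] and for profile plots.
#'
#' @inheritParams polygenic_reml
#' @param grid grid of h2 values (default 101 points on [0, 1]).
#' @return data.frame with columns `h2` and `loglik`.
#' @export
reml_profile <- function(values, kin, grid = seq(0, 1, length.out = 101)) {
  values <- values[!is.na(values)]
  ids <- names(values)
  n <- length(values)
  ed <- relationship_eigen(kin, ids)
  z <- rotate_eigen(ed, as.numeric(values))
  w <- rotate_eigen(ed, rep(1, n))
  data.frame(h2 = grid,
             loglik = vapply(grid, reml_loglik_h2, numeric(1),
                             d = ed$d, z = z, w = w, n = n))
}

#' @method print polygenic_fit
#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("Polygenic REML fit: %s (n = %d)\n", x$trait_name, x$n_used))
  cat(sprintf("  h2 = %.3f%s  sigma2_g = %.4g  sigma2_e = %.4g\n",
              x$h2,
              if (is.na(x$se_h2)) "" else sprintf(" (SE %.3f)", x$se_h2),
              x$sigma2_g, x$sigma2_e))
  cat(sprintf("  REML logLik = %.4f; LRT vs sigma2_g=0: %.3f, p = %.3g\n",
              x$loglik, x$lrt, x$lrt_p))
  invisible(x)
}

#' @method summary polygenic_fit
#' @export
summary.polygenic_fit <- function(object, ...) object

#' @export
coef.polygenic_fit <- function(object, ...) {
  c(mu = object$mu, sigma2_g = object$sigma2_g, sigma2_e = object$sigma2_e,
    h2 = object$h2)
}

#' @export
logLik.polygenic_fit <- function(object, ...) {
  structure(object$loglik, df = 3, class = "logLik")
}

#' Heritability table for one trait
#'
#' Assembles, for a single phenotype, the cross-sectional heritabilities
#' at each visit, the growth-curve slope heritability, the OLS slope
#' heritability, and the measured-versus-fitted correlation -- restricted
#' to participants with both visits so that all four estimates are
#' comparable.
#'
#' @param pheno data.frame with columns `person_id`, `visit1`, `visit2`,
#'   `ols_slope`, `gc_slope` (person-level, already residualized).
#' @param kin a [kinship()] matrix.
#' @param trait_name label.
#' @param gc_cor optional measured-vs-growth-curve correlation(s) (e.g.
#'   from [fitted_measured_cor()]); averaged into one reported value.
#' @return One-row data.frame with trait, n, h2 for each phenotype class,
#'   gc_cor, and per-column notes where an estimate failed.
#' @export
heritability_table <- function(pheno, kin, trait_name = "trait",
                               gc_cor = NA_real_) {
  keep <- !is.na(pheno$visit1) & !is.na(pheno$visit2)
  ph <- pheno[keep, , drop = FALSE]
  cell <- function(col) {
    v <- stats::setNames(ph[[col]], ph$person_id)
    tryCatch(polygenic_reml(v, kin, trait_name)$h2,
             error = function(e) NA_real_)
  }
  data.frame(trait = trait_name, n = nrow(ph),
             h2_visit1 = cell("visit1"), h2_visit2 = cell("visit2"),
             gc_cor = mean(gc_cor, na.rm = TRUE),
             h2_gc_slope = cell("gc_slope"),
             h2_ols_slope = cell("ols_slope"))
}
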