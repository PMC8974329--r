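#' Kinship matrix of a pedigree
#'
#' Computes kinship coefficients phi(i,j) -- the probability that one
#' allele drawn at random from i and one from j are identical by descent
#' -- by the standard recursive algorithm: individuals are processed with
#' parents before children; for a non-founder i with parents p and q,
#' phi(i,j) = (phi(p,j) + phi(q,j)) / 2 for any already-processed j != i,
#' and phi(i,i) = (1 + phi(p,q)) / 2. Founders are mutually unrelated and
#' non-inbred. Kinship is computed per family; cross-family kinship is 0
#' because families are independent sampling units.
#'
#' @param ped a [pedigree()] object.
#' @return An object of class `kinship_matrix`: list with `ids`, `fids`
#'   and the symmetric matrix `phi` (dimnames = ids, input order).
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (fam in unique(ped$fid)) {
    rows <- which(ped$fid == fam)
    sub <- ped[rows, , drop = FALSE]
    phi[rows, rows] <- kinship_one_family(sub)
  }
  structure(list(ids = ped$id, fids = ped$fid, phi = phi),
            class = "kinship_matrix")
}

kinship_one_family <- function(sub) {
  m <- nrow(sub)
  ord <- peel_order(sub)
  phi <- matrix(0, m, m)
  fa <- match(sub$father, sub$id)
  mo <- match(sub$mother, sub$id)
  done <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {                      # founder
      phi[i, i] <- 0.5
      # unrelated to everything already placed (ancestors precede children,
      # so nothing placed can descend from i)
    } else {
      if (length(done) > 0) {
        v <- 0.5 * (phi[fa[i], done] + phi[mo[i], done])
        phi[i, done] <- v
        phi[done, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
    done <- c(done, i)
  }
  phi
}

#' Monte-Carlo kinship by gene dropping
#'
#' Independent oracle for [kinship()]: drops a biallelic-free abstract
#' locus through the pedigree `n_drops` times (each founder carries two
#' uniquely labelled alleles; each child inherits one allele from each
#' parent uniformly at random) and estimates phi(i,j) as the Monte-Carlo
#' probability that one random allele of i and one of j are identical by
#' descent.
#'
#' @param ped a [pedigree()] object (single or multiple families).
#' @param n_drops number of replicate drops.
#' @return List with matrices `phi` (estimates) and `se` (Monte-Carlo
#'   standard errors), dimnames = ids.
#' @export
kinship_mc <- function(ped, n_drops = 2e5) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  R <- as.integer(n_drops)
  # allele label matrices, individuals x replicates
  a1 <- matrix(0L, n, R)
  a2 <- matrix(0L, n, R)
  lab <- 0L
  for (fam in unique(ped$fid)) {
    rows <- which(ped$fid == fam)
    sub <- ped[rows, , drop = FALSE]
    ord <- peel_order(sub)
    fa <- match(sub$father, sub$id)
    mo <- match(sub$mother, sub$id)
    for (i in ord) {
      gi <- rows[i]
      if (is.na(fa[i])) {
        a1[gi, ] <- lab + 1L
        a2[gi, ] <- lab + 2L
        lab <- lab + 2L
      } else {
        gf <- rows[fa[i]]; gm <- rows[mo[i]]
        pick <- stats::runif(R) < 0.5
        a1[gi, ] <- ifelse(pick, a1[gf, ], a2[gf, ])
        pick <- stats::runif(R) < 0.5
        a2[gi, ] <- ifelse(pick, a1[gm, ], a2[gm, ])
      }
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (ped$fid[i] != ped$fid[j]) next
      x <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
            (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
      phi[i, j] <- phi[j, i] <- mean(x)
      se[i, j] <- se[j, i] <- stats::sd(x) / sqrt(R)
    }
  }
  list(phi = phi, se = se)
}

#' @method print kinship_matrix
#' @export
print.kinship_matrix <- function(x, ...) {
  cat("Kinship matrix:", length(x$ids), "individuals,",
      length(unique(x$fids)), "family(ies)\n")
  cat("mean off-diagonal phi:",
      format(mean(x$phi[upper.tri(x$phi)]), digits = 4), "\n")
  invisible(x)
}

#' @method as.matrix kinship_matrix
#' @export
as.matrix.kinship_matrix <- function(x, ...) x$phi

#' Write kinship coefficients to file
#'
#' `format = "long"` writes a CSV with columns id1, id2, phi (upper
#' triangle including the diagonal, within-family pairs only);
#' `format = "matrix"` writes the square matrix with an id header row.
#'
#' @param kin a `kinship_matrix`.
#' @param path output path.
#' @param format `"long"` or `"matrix"`.
#' @export
write_kinship <- function(kin, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.csv(as.data.frame(kin$phi), path, row.names = TRUE)
  } else {
    n <- length(kin$ids)
    idx <- which(upper.tri(kin$phi, diag = TRUE) &
                   outer(kin$fids, kin$fids, "=="), arr.ind = TRUE)
    long <- data.frame(id1 = kin$ids[idx[, 1]], id2 = kin$ids[idx[, 2]],
                       phi = kin$phi[idx])
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
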