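#' Per-sibling survival exceptionality
#'
#' The exceptionality of a sibling is the negative log tail probability of
#' their survival status under the reference life table. For a sibling
#' dead at age T it is -log S(T). For a sibling alive at age t it is the
#' expected eventual value E[-log S(T) | T > t]: because -log S(T) is
#' unit-exponential when T follows the table, the conditional excess has
#' mean 1, giving the closed form -log S(t) + 1. A value of 1 is the
#' per-sib expectation under the table, and larger values indicate
#' survival more exceptional than the population's.
#'
#' @param table a [lifetable()].
#' @param sex,birth_year,age_years,vital_status sibling attributes
#'   (vectorised; `vital_status` is "alive" or "dead", `age_years` is age
#'   at death if dead, current age if alive).
#' @return Non-negative exceptionality scores.
#' @export
sib_exceptionality <- function(table, sex, birth_year, age_years,
                               vital_status) {
  n <- max(length(sex), length(birth_year), length(age_years),
           length(vital_status))
  sex <- rep_len(sex, n); birth_year <- rep_len(birth_year, n)
  age_years <- rep_len(age_years, n); vital_status <- rep_len(vital_status, n)
  bad <- is.na(age_years) | is.na(vital_status) | is.na(sex) |
    is.na(birth_year)
  if (any(bad))
    stop("missing age/vital status/sex/birth year for sibling(s) at position: ",
         paste(which(bad), collapse = ", "))
  if (!all(vital_status %in% c("alive", "dead")))
    stop("vital_status must be 'alive' or 'dead'")
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- survival_prob(table, sex[i], birth_year[i], age_years[i])
    out[i] <- -log(s) + (vital_status[i] == "alive")
  }
  out
}

#' Family Longevity Selection Score for one sibship
#'
#' Two components. The first sums each sibling's survival exceptionality
#' and subtracts the sibship size: because the per-sib expectation of
#' -log S(T) under the table is exactly 1, the centering makes the
#' expected value independent of sibship size, and a value of zero means
#' survival exactly as expected from the life tables. The second adds a
#' bonus for each living sibling, favouring larger families available for
#' prospective follow-up.
#'
#' Siblings with unknown vital status or age are excluded from the sum
#' and reported in `n_excluded`.
#'
#' @param sibs data.frame of proband-generation siblings with columns
#'   `sex`, `birth_year`, `age_years`, `vital_status` (and optionally
#'   `fid`).
#' @param table a [lifetable()].
#' @param bonus_per_living bonus added per living sibling (default 0.5;
#'   the original scoring coefficient is defined in the score's own
#'   methodology literature, so the value is a configuration choice here).
#' @return An object of class `sibship_score`: one-row data.frame with
#'   family_id, n_sibs, n_alive, n_excluded, exceptionality_sum,
#'   centered_component, bonus and floss.
#' @export
floss_score <- function(sibs, table, bonus_per_living = 0.5) {
  if (NROW(sibs) == 0) stop("empty sibship")
  fid <- if (!is.null(sibs$fid)) as.character(sibs$fid[1]) else NA_character_
  usable <- !is.na(sibs$vital_status) & !is.na(sibs$age_years) &
    !is.na(sibs$sex) & !is.na(sibs$birth_year)
  n_excluded <- sum(!usable)
  sc <- sibs[usable, , drop = FALSE]
  if (nrow(sc) == 0) stop("no scoreable siblings in sibship ", fid)
  exc <- sib_exceptionality(table, sc$sex, sc$birth_year, sc$age_years,
                            sc$vital_status)
  n_sibs <- nrow(sc)
  n_alive <- sum(sc$vital_status == "alive")
  centered <- sum(exc) - n_sibs
  bonus <- bonus_per_living * n_alive
  out <- data.frame(family_id = fid, n_sibs = n_sibs, n_alive = n_alive,
                    n_excluded = n_excluded,
                    exceptionality_sum = sum(exc),
                    centered_component = centered, bonus = bonus,
                    floss = centered + bonus)
  class(out) <- c("sibship_score", "data.frame")
  out
}

#' Study eligibility of a family
#'
#' A family is eligible when its sibship score reaches the threshold
#' (default 7) and the family structure contains a proband, at least one
#' living proband-generation sibling, and at least one offspring.
#'
#' @param family a [pedigree()] restricted to one family, with a
#'   `generation` column ("proband"/"offspring"/...), `vital_status`, and
#'   optionally a logical `is_proband` column singling out the index
#'   sibling (otherwise the oldest proband-generation member is taken).
#' @param score a `sibship_score` for the family's proband sibship.
#' @param threshold minimum score (default 7, inclusive).
#' @return List with `eligible` (logical) and `reasons` (character vector
#'   of failed criteria, empty when eligible).
#' @export
floss_eligible <- function(family, score, threshold = 7) {
  reasons <- character(0)
  if (score$floss < threshold)
    reasons <- c(reasons, "score below threshold")
  gen <- family$generation
  if (is.null(gen)) stop("family pedigree needs a 'generation' column")
  pro <- which(gen == "proband")
  if (length(pro) == 0) {
    reasons <- c(reasons, "no proband")
  } else {
    idx <- if (!is.null(family$is_proband) && any(family$is_proband %in% TRUE))
      which(family$is_proband %in% TRUE)[1]
    else pro[which.max(family$age_years[pro])]
    sibs <- setdiff(pro, idx)
    living_sib <- any(family$vital_status[sibs] == "alive", na.rm = TRUE)
    if (!living_sib) reasons <- c(reasons, "no living sibling")
  }
  if (!any(gen == "offspring")) reasons <- c(reasons, "no offspring")
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Score every family in a pedigree
#'
#' Applies [floss_score()] to each family's proband-generation sibship and
#' [floss_eligible()] to the family, returning one row per family.
#'
#' @param ped a [pedigree()] with `generation`, `vital_status`,
#'   `age_years`, `birth_year` columns.
#' @param table a [lifetable()].
#' @param bonus_per_living see [floss_score()].
#' @param threshold see [floss_eligible()].
#' @return data.frame with one row per family: the `sibship_score` fields
#'   plus `eligible` and `reasons` (semicolon-separated).
#' @export
floss_table <- function(ped, table, bonus_per_living = 0.5, threshold = 7) {
  stopifnot(inherits(ped, "pedigree"))
  rows <- lapply(unique(ped$fid), function(fam) {
    sub <- ped[ped$fid == fam, , drop = FALSE]
    sibs <- sub[sub$generation == "proband", , drop = FALSE]
    sc <- floss_score(sibs, table, bonus_per_living)
    el <- floss_eligible(sub, sc, threshold)
    sc$eligible <- el$eligible
    sc$reasons <- paste(el$reasons, collapse = "; ")
    sc$family_id <- fam
    sc
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}
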