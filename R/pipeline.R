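#' End-to-end synthetic-study experiment
#'
#' Runs the full methodological pipeline on one synthetic cohort:
#' simulate pedigrees, lifespans and two-visit phenotypes; score each
#' family's proband sibship; adjust visit values for sex, age, age
#' squared and field site; estimate naive OLS change slopes and
#' growth-curve (empirical-Bayes) slopes; and estimate kinship-based
#' heritability of the visit values and of both slope phenotypes,
#' restricted to participants with both visits. Slope phenotypes are
#' adjusted for sex, baseline age, baseline age squared and field site.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory: pedigree, life-table, phenotype,
#'   score and heritability files are written there with a JSON manifest
#'   of config, seed and file digests.
#' @return Object of class `famlong_experiment`: list with `floss`
#'   (per-family score table), `growth` (the [fit_growth_curve()]
#'   object), `h2_table` (one-row heritability table), `recovery`
#'   (diagnostics against simulation truth) and `config`.
#' @export
run_experiment <- function(config = sim_config(), out_dir = NULL) {
  sim <- simulate_study(config)
  ped <- sim$ped; records <- sim$records

  fl <- floss_table(ped, sim$lifetable)

  # visit-level covariate adjustment (same-visit age)
  records$adj_value <- NA_real_
  for (v in 1:2) {
    sel <- records$visit == v
    records$adj_value[sel] <- residualize(records$value[sel],
                                          records$sex[sel],
                                          records$age_at_visit[sel],
                                          records$field_site[sel])
  }

  gfit <- fit_growth_curve(data.frame(person_id = records$person_id,
                                      age = records$age_at_visit,
                                      value = records$adj_value,
                                      visit = records$visit),
                           age_center = config$age_center)

  ols <- ols_slopes(data.frame(person_id = records$person_id,
                               visit = records$visit,
                               visit_date = records$visit_date,
                               value = records$value))

  v1 <- records[records$visit == 1, ]
  v2 <- records[records$visit == 2, ]
  base <- v1[match(ols$person_id, v1$person_id), ]
  # slope phenotypes: adjust for sex, baseline age, baseline age^2, site
  ols_adj <- residualize(ols$ols_slope, base$sex, base$age_at_visit,
                         base$field_site)
  pp <- gfit$per_person
  gbase <- v1[match(pp$person_id, v1$person_id), ]
  gc_adj <- residualize(pp$blup_slope, gbase$sex, gbase$age_at_visit,
                        gbase$field_site)

  pheno <- data.frame(person_id = ols$person_id,
                      visit1 = v1$adj_value[match(ols$person_id,
                                                  v1$person_id)],
                      visit2 = v2$adj_value[match(ols$person_id,
                                                  v2$person_id)],
                      ols_slope = ols_adj,
                      gc_slope = gc_adj[match(ols$person_id, pp$person_id)])
  h2_table <- heritability_table(pheno, sim$kin, trait_name = "generic",
                                 gc_cor = fitted_measured_cor(gfit))

  tr <- sim$truth
  m <- match(pp$person_id, tr$person_id)
  recovery <- list(
    components_true = attr(tr, "components"),
    G_hat = gfit$G, sigma2_e_hat = gfit$sigma2_e,
    cor_blup_true_slope = stats::cor(pp$blup_slope, tr$true_slope[m],
                                     use = "complete.obs"),
    h2_slope_generating = config$h2_slope)

  out <- list(floss = fl, growth = gfit, h2_table = h2_table,
              recovery = recovery, config = config, sim = sim)
  class(out) <- "famlong_experiment"
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @method print famlong_experiment
#' @export
print.famlong_experiment <- function(x, ...) {
  cat("Synthetic family-longevity experiment\n")
  cat(sprintf("  %d families scored; mean sibship score %.3f; %d eligible\n",
              nrow(x$floss), mean(x$floss$floss), sum(x$floss$eligible)))
  cat(sprintf("  growth fit: %d persons; residual variance %.3g (true %.3g)\n",
              x$growth$n_persons, x$growth$sigma2_e,
              x$recovery$components_true[["sigma2_e"]]))
  cat("  heritability table (both-visit restriction):\n")
  print(x$h2_table, row.names = FALSE)
  cat(sprintf("  generating slope h2: %.2f; cor(BLUP slope, true slope): %.3f\n",
              x$recovery$h2_slope_generating, x$recovery$cor_blup_true_slope))
  invisible(x)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_ped(x$sim$ped, p("pedigree.ped"))
  write_lifetable(x$sim$lifetable, p("lifetable.csv"))
  utils::write.csv(x$sim$records, p("phenotypes.csv"), row.names = FALSE)
  utils::write.csv(x$sim$truth, p("truth.csv"), row.names = FALSE)
  utils::write.csv(x$floss, p("floss.csv"), row.names = FALSE)
  utils::write.csv(x$h2_table, p("h2_table.csv"), row.names = FALSE)
  files <- c("pedigree.ped", "lifetable.csv", "phenotypes.csv",
             "truth.csv", "floss.csv", "h2_table.csv")
  manifest <- list(seed = x$config$seed,
                   config = x$config[setdiff(names(x$config), "")],
                   digests = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Rare-variant linkage demonstration scenario
#'
#' Configuration for [run_raredrop_demo()]: a set of equally structured
#' two-generation families (sibship of `sibship_size`, each sibling with
#' a spouse and `offspring_per_sib` offspring), of which `n_linked` carry
#' one family-private causal variant introduced by a heterozygous
#' sibship-founder parent. Carriers' phenotypes are shifted by
#' `effect_size` residual standard deviations on top of a polygenic
#' background.
#'
#' @param n_linked families carrying a private causal variant.
#' @param n_null families without any causal variant.
#' @param sibship_size,offspring_per_sib family structure.
#' @param effect_size carrier shift in residual-SD units.
#' @param sigma2_g,sigma2_e polygenic and residual variance.
#' @param gwas_threshold genome-wide significance threshold for the
#'   association comparator.
#' @param seed integer seed.
#' @export
raredrop_config <- function(n_linked = 50, n_null = 30,
                            sibship_size = 3, offspring_per_sib = 1,
                            effect_size = 3,
                            sigma2_g = 0.5, sigma2_e = 1,
                            gwas_threshold = 5e-8, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "raredrop_config"
  cfg
}

# Fixed-structure family used by the rare-variant demo.
raredrop_family <- function(fid, sibship_size, offspring_per_sib) {
  rows <- list(
    data.frame(fid = fid, id = "P.F", father = NA, mother = NA,
               sex = "male", generation = "founder", enrolled = FALSE),
    data.frame(fid = fid, id = "P.M", father = NA, mother = NA,
               sex = "female", generation = "founder", enrolled = FALSE))
  for (k in seq_len(sibship_size)) {
    sid <- paste0("S", k)
    sex <- if (k %% 2 == 1) "male" else "female"
    rows[[length(rows) + 1L]] <- data.frame(
      fid = fid, id = sid, father = "P.F", mother = "P.M", sex = sex,
      generation = "proband", enrolled = TRUE)
    spid <- paste0(sid, ".sp")
    rows[[length(rows) + 1L]] <- data.frame(
      fid = fid, id = spid, father = NA, mother = NA,
      sex = if (sex == "male") "female" else "male",
      generation = "spouse-control", enrolled = TRUE)
    for (j in seq_len(offspring_per_sib)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fid = fid, id = paste0(sid, ".O", j),
        father = if (sex == "male") sid else spid,
        mother = if (sex == "male") spid else sid,
        sex = if (j %% 2 == 1) "female" else "male",
        generation = "offspring", enrolled = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Rare-variant linkage versus association demonstration
#'
#' Gene-drops one private causal variant per linked family, simulates a
#' polygenic phenotype with a carrier shift, computes per-family
#' variance-component linkage LODs at the locus (using the
#' simulation-true IBD), aggregates them into an HLOD, and runs the
#' pooled single-variant score test on every private variant. The
#' summary reports whether the linkage-versus-association dissociation
#' occurred: HLOD above 3 while the smallest single-variant p-value
#' stays above the genome-wide threshold.
#'
#' @param config a [raredrop_config()].
#' @return Object of class `raredrop_demo`: list with `hlod` (an
#'   [hlod()] object), `assoc` (association results incl. `min_p`),
#'   `lods` (per-family data.frame), `dissociation` (logical),
#'   `carrier_freq` (per-variant pooled allele frequencies) and
#'   `config`.
#' @export
run_raredrop_demo <- function(config = raredrop_config()) {
  n_fam <- config$n_linked + config$n_null
  peds <- lapply(seq_len(n_fam), function(i)
    raredrop_family(sprintf("L%03d", i), config$sibship_size,
                    config$offspring_per_sib))
  ped <- do.call(rbind, peds)
  ped$id <- paste(ped$fid, ped$id, sep = ":")
  ped$father <- ifelse(is.na(ped$father), NA,
                       paste(ped$fid, ped$father, sep = ":"))
  ped$mother <- ifelse(is.na(ped$mother), NA,
                       paste(ped$fid, ped$mother, sep = ":"))
  ped <- pedigree(ped)
  kin <- kinship(ped)

  fams <- unique(ped$fid)
  dose_cols <- list(); y_all <- c(); Pi_blocks <- list()
  effect <- config$effect_size * sqrt(config$sigma2_e)
  for (i in seq_along(fams)) {
    set.seed(family_seed(config$seed, i, 11L))
    sel <- which(ped$fid == fams[i])
    fam_ped <- ped[sel, , drop = FALSE]
    class(fam_ped) <- c("pedigree", "data.frame")
    linked <- i <= config$n_linked
    carriers <- if (linked)
      stats::setNames(1L, paste0(fams[i], ":P.F")) else NULL
    drop <- gene_drop(fam_ped, founder_carriers = carriers)
    Pi <- ibd_matrix(drop)
    A <- 2 * kin$phi[sel, sel, drop = FALSE]
    L <- chol_psd(A)
    g <- as.numeric(L %*% stats::rnorm(length(sel))) * sqrt(config$sigma2_g)
    y <- g + stats::rnorm(length(sel), 0, sqrt(config$sigma2_e)) +
      effect * drop$dosage
    names(y) <- fam_ped$id
    phen <- y[fam_ped$enrolled]
    y_all <- c(y_all, phen)
    Pi_blocks[[fams[i]]] <- Pi[names(phen), names(phen)]
    if (linked) {
      cm <- carrier_matrix(drop)
      dvec <- stats::setNames(rep(0L, length(phen)), names(phen))
      dvec[rownames(cm)[rownames(cm) %in% names(phen)]] <-
        cm[rownames(cm) %in% names(phen), 1]
      dose_cols[[fams[i]]] <- dvec
    }
  }
  # joint variance-component linkage: per-family lod contributions at the
  # joint estimates (can be negative for unlinked families)
  Pi_all <- matrix(0, length(y_all), length(y_all),
                   dimnames = list(names(y_all), names(y_all)))
  for (b in Pi_blocks) Pi_all[rownames(b), colnames(b)] <- b
  vc <- vc_linkage(y_all, Pi_all, kin)
  lods <- vc$per_family

  hl <- hlod(lods)
  if (length(dose_cols) > 0) {
    D <- sapply(dose_cols, function(d) {
      out <- rep(0L, length(y_all)); names(out) <- names(y_all)
      out[names(d)] <- d; out
    })
    assoc <- single_variant_association(y_all, D)
    carrier_freq <- colSums(D) / (2 * length(y_all))
  } else {
    assoc <- list(per_variant = NULL, min_p = NA_real_)
    carrier_freq <- numeric(0)
  }
  dissociation <- isTRUE(hl$hlod > 3 &&
                           (is.na(assoc$min_p) ||
                              assoc$min_p > config$gwas_threshold))
  structure(list(hlod = hl, assoc = assoc, lods = lods,
                 joint_lod = vc$lod, dissociation = dissociation,
                 carrier_freq = carrier_freq, config = config),
            class = "raredrop_demo")
}

#' @method print raredrop_demo
#' @export
print.raredrop_demo <- function(x, ...) {
  cat("Rare lineage-specific variant demonstration\n")
  cat(sprintf("  %d families (%d with a private causal variant)\n",
              nrow(x$lods), x$config$n_linked))
  cat(sprintf("  HLOD = %.3f at alpha = %.3f; %d driving families (lod > 0.2)\n",
              x$hlod$hlod, x$hlod$alpha_hat,
              length(x$hlod$driving_families)))
  if (!is.na(x$assoc$min_p))
    cat(sprintf("  min single-variant p = %.3g (threshold %g); max pooled allele freq %.4f\n",
                x$assoc$min_p, x$config$gwas_threshold,
                if (length(x$carrier_freq)) max(x$carrier_freq) else NA))
  cat(sprintf("  linkage-vs-association dissociation: %s\n",
              if (x$dissociation) "YES" else "no"))
  invisible(x)
}
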