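#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' study design the package targets: two-generation families built
#' around a long-lived proband sibship (enrolled family size mean near 9,
#' within [3, 79]), Gompertz life-table lifespans, a first visit around
#' recruitment with a second visit 8-10 years later, and a quantitative
#' trait with heritable, correlated person-level intercepts and slopes
#' plus per-visit measurement error (scaled like systolic blood
#' pressure: between-person SD 10, slope SD 0.2/year, error SD ~3.9).
#'
#' @param n_families number of families.
#' @param sibship_mean,sibship_dispersion,sibship_range truncated
#'   negative-binomial proband-sibship size: 2 + NB(mu = sibship_mean - 2,
#'   size = sibship_dispersion), truncated to `sibship_range`.
#' @param offspring_mean Poisson mean offspring per sibling.
#' @param offspring_spouse_prob probability an offspring's spouse is
#'   enrolled.
#' @param max_family_size,min_family_size enrolled-size bounds (families
#'   are redrawn to respect them).
#' @param recruit_year first-visit calendar year.
#' @param gompertz_a,gompertz_b per-sex Gompertz hazard parameters.
#' @param proband_age_mean,proband_age_sd,offspring_age_mean,offspring_age_sd
#'   first-visit age distributions per generation (normal, truncated to
#'   plausible ranges).
#' @param visit_gap_range inter-visit years (uniform support).
#' @param age_center reference age (years): trajectories are lines in
#'   age - age_center, so `beta[1]` is the population mean value at that
#'   age and intercept deviations are person-level values there.
#' @param beta population intercept and slope.
#' @param sigma2_int,sigma2_slope,rho_01 total random-effect covariance.
#' @param h2_intercept,h2_slope heritable fractions of the intercept and
#'   slope variances.
#' @param sigma2_e per-visit measurement-error variance.
#' @param sex_effect,site_effects,age_effect nuisance covariate effects on
#'   the person level (removed downstream by residualization).
#' @param hazard_multiplier multiplies the proband-generation hazard
#'   (values < 1 enrich for exceptional survival).
#' @param visit2_dropout missing-at-random probability of a missing
#'   second visit.
#' @param seed integer seed; per-family substreams are derived from it so
#'   results do not depend on iteration order.
#' @return Object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_families = 150,
                       sibship_mean = 3, sibship_dispersion = 2,
                       sibship_range = c(2, 12),
                       offspring_mean = 1.05,
                       offspring_spouse_prob = 0.15,
                       max_family_size = 79, min_family_size = 3,
                       recruit_year = 2006,
                       gompertz_a = c(male = 1.1e-4, female = 6e-5),
                       gompertz_b = c(male = 0.085, female = 0.085),
                       proband_age_mean = 90.2, proband_age_sd = 6.6,
                       offspring_age_mean = 61.2, offspring_age_sd = 8.4,
                       visit_gap_range = c(8, 10),
                       age_center = 75,
                       beta = c(intercept = 100, slope = 0.5),
                       sigma2_int = 100, sigma2_slope = 0.04, rho_01 = 0.5,
                       h2_intercept = 0.4, h2_slope = 0.4,
                       sigma2_e = 15,
                       sex_effect = 3,
                       site_effects = c(A = -2, B = -0.5, C = 0.5, D = 2),
                       age_effect = 0.2,
                       hazard_multiplier = 1,
                       visit2_dropout = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(sigma2_int >= 0, sigma2_slope >= 0, sigma2_e >= 0,
            h2_intercept >= 0, h2_intercept <= 1,
            h2_slope >= 0, h2_slope <= 1,
            abs(rho_01) <= 1,
            min_family_size >= 3, max_family_size <= 79,
            visit_gap_range[1] >= 8, visit_gap_range[2] <= 10)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-family substream seed (order-independent).
family_seed <- function(seed, i, stage = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 16807 + stage * 69621) %%
               2147483647)
}

#' Simulate two-generation study pedigrees
#'
#' Each family is a proband sibship (with its two non-enrolled founder
#' parents included so that sibling kinship is represented), spouses for
#' every sibling with offspring, offspring of the siblings, and a
#' fraction of offspring spouses. Spouses are founders, genetically
#' unrelated to the sibship -- their role as internal controls in the
#' study design. Enrolled family sizes are kept within
#' `[min_family_size, max_family_size]`.
#'
#' @param config a [sim_config()].
#' @return A [pedigree()] with columns `generation` ("founder",
#'   "proband", "spouse-control", "offspring"), `enrolled` (logical),
#'   `birth_year`, `field_site` and `is_proband`.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- lapply(seq_len(config$n_families), function(i) {
    set.seed(family_seed(config$seed, i, 1L))
    simulate_one_family(config, i)
  })
  ped <- do.call(rbind, fams)
  # globally unique person ids
  ped$id <- paste(ped$fid, ped$id, sep = ":")
  ped$father <- ifelse(is.na(ped$father), NA,
                       paste(ped$fid, ped$father, sep = ":"))
  ped$mother <- ifelse(is.na(ped$mother), NA,
                       paste(ped$fid, ped$mother, sep = ":"))
  pedigree(ped)
}

simulate_one_family <- function(cfg, i) {
  fid <- sprintf("F%04d", i)
  site <- sample(names(cfg$site_effects), 1)
  for (try in 1:50) {
    s <- 2 + stats::rnbinom(1, mu = max(cfg$sibship_mean - 2, 0.01),
                            size = cfg$sibship_dispersion)
    s <- min(max(s, cfg$sibship_range[1]), cfg$sibship_range[2])
    n_off <- stats::rpois(s, cfg$offspring_mean)
    off_sp <- stats::runif(sum(n_off)) < cfg$offspring_spouse_prob
    size <- s + sum(n_off > 0) + sum(n_off) + sum(off_sp)
    if (size >= cfg$min_family_size && size <= cfg$max_family_size) break
  }
  rows <- list()
  add <- function(id, father, mother, sex, gen, enrolled, birth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fid = fid, id = id, father = father, mother = mother, sex = sex,
      generation = gen, enrolled = enrolled, birth_year = birth,
      field_site = site, stringsAsFactors = FALSE)
  }
  ryear <- cfg$recruit_year
  page <- function() round(trunc_norm(cfg$proband_age_mean,
                                      cfg$proband_age_sd, 70, 105))
  oage <- function() round(trunc_norm(cfg$offspring_age_mean,
                                      cfg$offspring_age_sd, 25, 88))
  add("P.F", NA, NA, "male", "founder", FALSE, ryear - page() - 25)
  add("P.M", NA, NA, "female", "founder", FALSE, ryear - page() - 25)
  osp_pos <- 0L
  for (k in seq_len(s)) {
    sid <- paste0("S", k)
    sex <- sample(c("male", "female"), 1)
    add(sid, "P.F", "P.M", sex, "proband", TRUE, ryear - page())
    if (n_off[k] > 0) {
      spid <- paste0("S", k, ".sp")
      spsex <- if (sex == "male") "female" else "male"
      add(spid, NA, NA, spsex, "spouse-control", TRUE, ryear - page())
      fa <- if (sex == "male") sid else spid
      mo <- if (sex == "male") spid else sid
      for (j in seq_len(n_off[k])) {
        oid <- paste0("S", k, ".O", j)
        osex <- sample(c("male", "female"), 1)
        add(oid, fa, mo, osex, "offspring", TRUE, ryear - oage())
        osp_pos <- osp_pos + 1L
        if (off_sp[osp_pos]) {
          add(paste0(oid, ".sp"), NA, NA,
              if (osex == "male") "female" else "male",
              "spouse-control", TRUE, ryear - oage())
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  pro <- which(out$generation == "proband")
  out$is_proband <- FALSE
  out$is_proband[pro[which.min(out$birth_year[pro])]] <- TRUE
  out
}

trunc_norm <- function(mean, sd, lo, hi) {
  for (k in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Life table implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return Two-sex Gompertz [lifetable()] covering the simulated cohorts.
#' @export
sim_lifetable <- function(config) {
  make_gompertz_table2(a = config$gompertz_a, b = config$gompertz_b,
                       cohort_start = 1870, cohort_end = 1990,
                       max_age = 110)
}

#' Simulate lifespans and vital status for the proband generation
#'
#' Death ages are drawn by inverse transform from the life table
#' (optionally with the hazard scaled by `hazard_multiplier`; values
#' below 1 make survival more exceptional). Members still alive at the
#' recruitment-year census are recorded alive at their census age.
#'
#' @param ped pedigree from [simulate_pedigrees()].
#' @param table a [lifetable()] (defaults to the configured one).
#' @param config a [sim_config()].
#' @return `ped` with `vital_status` and `age_years` filled for the
#'   proband generation.
#' @export
simulate_lifespans <- function(ped, config, table = sim_lifetable(config)) {
  ped$vital_status <- NA_character_
  ped$age_years <- NA_real_
  fams <- unique(ped$fid)
  for (i in seq_along(fams)) {
    set.seed(family_seed(config$seed, i, 2L))
    rows <- which(ped$fid == fams[i] & ped$generation == "proband")
    for (r in rows) {
      u <- stats::runif(1)
      # hazard multiplier m: -log S(T) = Exp(1)/m, i.e. quantile at u^(1/m)
      uu <- exp(log(u) / config$hazard_multiplier)
      T_death <- survival_quantile(table, ped$sex[r], ped$birth_year[r], uu)
      census_age <- config$recruit_year - ped$birth_year[r]
      if (T_death > census_age) {
        ped$vital_status[r] <- "alive"
        ped$age_years[r] <- census_age
      } else {
        ped$vital_status[r] <- "dead"
        ped$age_years[r] <- T_death
      }
    }
  }
  ped
}

#' Simulate a heritable person-level trait on a pedigree
#'
#' Draws y = g + e with genetic values g having covariance
#' 2*Phi*h2*sigma2 within each family (via a symmetric square root of
#' the family kinship block) and independent environmental deviations
#' with variance (1-h2)*sigma2.
#'
#' @param ped a [pedigree()].
#' @param kin its [kinship()] matrix (computed if missing).
#' @param h2 heritability in [0, 1].
#' @param sigma2 total variance.
#' @return Named vector over all pedigree members.
#' @export
simulate_polygenic_trait <- function(ped, h2, sigma2 = 1, kin = kinship(ped)) {
  n <- nrow(ped)
  y <- numeric(n)
  for (fam in unique(ped$fid)) {
    sel <- which(ped$fid == fam)
    A <- 2 * kin$phi[sel, sel, drop = FALSE]
    L <- chol_psd(A)
    g <- as.numeric(L %*% stats::rnorm(length(sel))) * sqrt(h2 * sigma2)
    e <- stats::rnorm(length(sel), 0, sqrt((1 - h2) * sigma2))
    y[sel] <- g + e
  }
  stats::setNames(y, ped$id)
}

#' Simulate two-visit phenotype records with known truth
#'
#' Person-level true intercepts and slopes are beta plus genetic and
#' environmental deviations: genetic deviations within a family have
#' covariance 2*Phi times the genetic component of the random-effect
#' covariance, environmental deviations are independent, and the genetic
#' fractions are `h2_intercept` and `h2_slope`. The intercept-slope
#' correlation `rho_01` is applied to the genetic and environmental parts
#' alike, so the total covariance G has exactly that correlation when the
#' two heritabilities are equal. Each person's trajectory is a line in
#' age: observed values are the person's line evaluated at the visit age
#' (centered at `age_center`) plus independent N(0, sigma2_e) error,
#' with sex, field-site and baseline-age nuisance effects added to the
#' level.
#'
#' @param ped pedigree from [simulate_pedigrees()].
#' @param config a [sim_config()].
#' @param kin kinship matrix (computed if missing).
#' @return List with `records` (person_id, visit, visit_date,
#'   age_at_visit, time, value, sex, field_site, fid) and `truth`
#'   (person_id, true_intercept, true_slope, genetic/environmental parts,
#'   and the generating variance components as attributes).
#' @export
simulate_phenotypes <- function(ped, config, kin = kinship(ped)) {
  stopifnot(inherits(config, "sim_config"))
  s0 <- sqrt(config$sigma2_int); s1 <- sqrt(config$sigma2_slope)
  rho <- config$rho_01
  Gg <- outer(c(sqrt(config$h2_intercept) * s0, sqrt(config$h2_slope) * s1),
              c(sqrt(config$h2_intercept) * s0, sqrt(config$h2_slope) * s1)) *
    matrix(c(1, rho, rho, 1), 2)
  Ge <- outer(c(sqrt(1 - config$h2_intercept) * s0,
                sqrt(1 - config$h2_slope) * s1),
              c(sqrt(1 - config$h2_intercept) * s0,
                sqrt(1 - config$h2_slope) * s1)) *
    matrix(c(1, rho, rho, 1), 2)
  Lg <- chol_psd(Gg); Le <- chol_psd(Ge)

  fams <- unique(ped$fid)
  rec <- list(); tru <- list()
  for (i in seq_along(fams)) {
    set.seed(family_seed(config$seed, i, 3L))
    sel <- which(ped$fid == fams[i])
    nf <- length(sel)
    A <- 2 * kin$phi[sel, sel, drop = FALSE]
    LA <- chol_psd(A)
    g <- LA %*% matrix(stats::rnorm(nf * 2), nf, 2) %*% t(Lg)
    e <- matrix(stats::rnorm(nf * 2), nf, 2) %*% t(Le)
    u <- g + e
    sub <- ped[sel, , drop = FALSE]
    enr <- which(sub$enrolled)
    if (length(enr) == 0) next
    age1 <- config$recruit_year - sub$birth_year[enr]
    level_shift <- ifelse(sub$sex[enr] == "male", config$sex_effect, 0) +
      config$site_effects[sub$field_site[enr]] +
      config$age_effect * (age1 - 75)
    gap <- stats::runif(length(enr), config$visit_gap_range[1],
                        config$visit_gap_range[2])
    d1 <- as.Date(sprintf("%d-06-30", config$recruit_year)) +
      round(stats::runif(length(enr), 0, 3 * 365.25))
    drop2 <- stats::runif(length(enr)) < config$visit2_dropout
    for (k in seq_along(enr)) {
      p <- enr[k]
      int_k <- config$beta[["intercept"]] + u[p, 1] + level_shift[k]
      slo_k <- config$beta[["slope"]] + u[p, 2]
      for (v in 1:2) {
        if (v == 2 && drop2[k]) next
        t_v <- if (v == 1) 0 else gap[k]
        age_v <- age1[k] + t_v
        rec[[length(rec) + 1L]] <- data.frame(
          person_id = sub$id[p], fid = fams[i], visit = v,
          visit_date = d1[k] + round(t_v * 365.25),
          age_at_visit = age_v, time = t_v,
          value = int_k + slo_k * (age_v - config$age_center) +
            stats::rnorm(1, 0, sqrt(config$sigma2_e)),
          sex = sub$sex[p], field_site = sub$field_site[p],
          stringsAsFactors = FALSE)
      }
      tru[[length(tru) + 1L]] <- data.frame(
        person_id = sub$id[p], fid = fams[i],
        true_intercept = int_k, true_slope = slo_k,
        g_intercept = g[p, 1], g_slope = g[p, 2],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  truth <- do.call(rbind, tru)
  attr(truth, "components") <- c(sigma2_int = config$sigma2_int,
                                 sigma2_slope = config$sigma2_slope,
                                 rho_01 = config$rho_01,
                                 h2_intercept = config$h2_intercept,
                                 h2_slope = config$h2_slope,
                                 sigma2_e = config$sigma2_e)
  list(records = records, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Pedigrees, life table, proband-generation lifespans and two-visit
#' phenotypes under one configuration and seed. Person ids are made
#' globally unique by prefixing the family id.
#'
#' @param config a [sim_config()].
#' @return List with `ped`, `kin`, `lifetable`, `records`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigrees(config)
  table <- sim_lifetable(config)
  ped <- simulate_lifespans(ped, config, table)
  kin <- kinship(ped)
  phe <- simulate_phenotypes(ped, config, kin)
  list(ped = ped, kin = kin, lifetable = table,
       records = phe$records, truth = phe$truth, config = config)
}
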