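test_that("minimum family: sibship of three with no offspring", {
  cfg <- sim_config(n_families = 1, sibship_mean = 3,
                    sibship_range = c(3, 3), offspring_mean = 0, seed = 1)
  ped <- simulate_pedigrees(cfg)
  expect_equal(sum(ped$enrolled), 3)
  expect_true(all(ped$generation[ped$enrolled] == "proband"))
})

test_that("default config produces family sizes near the study's mean", {
  cfg <- sim_config(n_families = 500, seed = 7)
  ped <- simulate_pedigrees(cfg)
  sizes <- tapply(ped$enrolled, ped$fid, sum)
  expect_gte(mean(sizes), 8)
  expect_lte(mean(sizes), 10.5)
  expect_true(all(sizes >= 3 & sizes <= 79))
})

test_that("generation is deterministic given config and seed", {
  cfg <- sim_config(n_families = 20, seed = 33)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$ped), as.data.frame(s2$ped))
  expect_identical(s1$records, s2$records)
  f1 <- withr::local_tempfile(fileext = ".ped")
  f2 <- withr::local_tempfile(fileext = ".ped")
  write_ped(s1$ped, f1); write_ped(s2$ped, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("lifespans respect the hazard multiplier stochastic ordering", {
  lt <- sim_lifetable(sim_config())
  mean_floss <- function(mult) {
    cfg <- sim_config(n_families = 120, seed = 13,
                      hazard_multiplier = mult)
    ped <- simulate_lifespans(simulate_pedigrees(cfg), cfg, lt)
    mean(floss_table(ped, lt)$floss)
  }
  expect_gt(mean_floss(0.5), mean_floss(1))
})

test_that("sibling genetic slope deviations have covariance 0.5 h2 sigma2", {
  # many sib-pair families; empirical cov of sib pairs vs 2*phi*sigma2_g
  cfg <- sim_config(n_families = 1500, sibship_mean = 2,
                    sibship_range = c(2, 2), offspring_mean = 0,
                    sigma2_slope = 0.04, h2_slope = 0.4, seed = 17)
  ped <- simulate_pedigrees(cfg)
  phe <- simulate_phenotypes(ped, cfg)
  tr <- phe$truth
  sib1 <- tr[grepl(":S1$", tr$person_id), ]
  sib2 <- tr[grepl(":S2$", tr$person_id), ]
  m <- match(sib1$fid, sib2$fid)
  cv <- cov(sib1$g_slope, sib2$g_slope[m])
  want <- 0.5 * 0.4 * 0.04
  se <- sd(sib1$g_slope * sib2$g_slope[m]) / sqrt(nrow(sib1))
  expect_lt(abs(cv - want), 3 * se)
})

test_that("zero slope heritability and zero noise give exact OLS recovery", {
  cfg <- sim_config(n_families = 40, sigma2_e = 0, seed = 19)
  sim <- simulate_study(cfg)
  v1 <- sim$records[sim$records$visit == 1, ]
  v2 <- sim$records[sim$records$visit == 2, ]
  m <- match(v1$person_id, v2$person_id)
  ok <- !is.na(m)
  slope <- (v2$value[m[ok]] - v1$value[ok]) /
    (v2$age_at_visit[m[ok]] - v1$age_at_visit[ok])
  tru <- sim$truth$true_slope[match(v1$person_id[ok],
                                    sim$truth$person_id)]
  expect_equal(slope, tru, tolerance = 1e-10)
})

test_that("generated files round-trip through the package readers", {
  cfg <- sim_config(n_families = 10, seed = 23)
  sim <- simulate_study(cfg)
  pf <- withr::local_tempfile(fileext = ".ped")
  lf <- withr::local_tempfile(fileext = ".csv")
  write_ped(sim$ped, pf); write_lifetable(sim$lifetable, lf)
  ped2 <- read_ped(pf)
  expect_equal(ped2$id, sim$ped$id)
  expect_equal(kinship(ped2)$phi, kinship(sim$ped)$phi)
  lt2 <- read_lifetable(lf)
  expect_equal(survival_prob(lt2, "female", 1915, 90),
               survival_prob(sim$lifetable, "female", 1915, 90))
})

test_that("config validation rejects out-of-band parameters", {
  expect_error(sim_config(h2_slope = 1.2))
  expect_error(sim_config(sigma2_e = -1))
  expect_error(sim_config(max_family_size = 100))
  expect_error(sim_config(visit_gap_range = c(5, 10)))
})
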