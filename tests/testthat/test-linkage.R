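test_that("gene dropping respects Mendelian transmission", {
  trio <- ped_trio()
  set.seed(1)
  # founder frequency 0: no carriers anywhere
  drop0 <- gene_drop(trio, freq = 0)
  expect_true(all(drop0$dosage == 0))
  # one heterozygous parent: child carrier frequency 1/2
  kid <- replicate(4000, {
    gene_drop(trio, founder_carriers = c(F = 1))$dosage[3]
  })
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(kid) - 0.5), 3 * se)
  # full sibs share half their alleles IBD on average
  sibs <- ped_sibs(2)
  set.seed(2)
  pi_ab <- replicate(3000, {
    ibd_matrix(gene_drop(sibs))["S1", "S2"]
  })
  expect_lt(abs(mean(pi_ab) - 0.5), 3 * sd(pi_ab) / sqrt(3000))
  expect_true(all(pi_ab %in% c(0, 0.5, 1)))
})

test_that("locus IBD matrix has exact structural values", {
  ped <- ped_threegen()
  set.seed(3)
  for (r in 1:40) {
    drop <- gene_drop(ped)
    Pi <- ibd_matrix(drop)
    expect_equal(unname(diag(Pi)), rep(1, nrow(ped)))
    expect_equal(Pi["GF", "As"], 0)           # founders, different lineages
    expect_equal(Pi["A", "C"], 0.5)           # parent-offspring, always
    expect_equal(Pi["GF", "C"] %in% c(0, 0.5), TRUE)
  }
  # monozygotic duplication fixture: cloned genotype rows share everything
  clone <- data.frame(fid = "1", id = c("t1", "t2"), allele1 = 1L,
                      allele2 = 2L, dosage = 0L)
  class(clone) <- c("gene_drop", "data.frame")
  attr(clone, "causal") <- integer(0); attr(clone, "variant_of") <- character(0)
  expect_equal(ibd_matrix(clone)["t1", "t2"], 1)
})

test_that("per-family LOD is zero at the boundary and positive under linkage", {
  fam <- demo_family(3, 2)
  kin <- kinship(fam)
  set.seed(5)
  nulls <- replicate(150, {
    drop <- gene_drop(fam)
    y <- setNames(rnorm(nrow(fam)), fam$id)[fam$enrolled]
    family_vc_lod(y, ibd_matrix(drop), kin)$lod
  })
  expect_true(all(nulls >= 0))
  expect_gte(mean(nulls == 0), 0.45)
  expect_lt(mean(nulls), 0.15)
  # strong carrier shift in a large family is detected
  big <- demo_family(8, 2)
  kb <- kinship(big)
  set.seed(6)
  pow <- replicate(60, {
    drop <- gene_drop(big, founder_carriers = setNames(1L, "X:P.F"))
    y <- setNames(rnorm(nrow(big)) + 3 * drop$dosage, big$id)[big$enrolled]
    family_vc_lod(y, ibd_matrix(drop), kb)$lod
  })
  expect_gte(mean(pow > 1), 0.7)
})

test_that("family LOD is invariant to phenotype location and scale", {
  fam <- demo_family(4, 2)
  kin <- kinship(fam)
  set.seed(8)
  drop <- gene_drop(fam, founder_carriers = setNames(1L, "X:P.F"))
  y <- setNames(rnorm(nrow(fam)) + 2 * drop$dosage, fam$id)[fam$enrolled]
  Pi <- ibd_matrix(drop)
  l1 <- family_vc_lod(y, Pi, kin)$lod
  l2 <- family_vc_lod(100 + 7 * y, Pi, kin)$lod
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("hlod matches its closed cases and the brute-force grid", {
  expect_equal(hlod(rep(0, 8))$hlod, 0)
  one <- hlod(c(3, rep(0, 9)))
  expect_equal(one$hlod, 3)
  expect_equal(one$alpha_hat, 1)
  brute <- function(L) max(sapply(seq(0, 1, by = 0.001), function(a)
    sum(log10(a * 10^L + 1 - a))))
  L <- c(2, 2, -1, -1, -1)
  expect_equal(hlod(L)$hlod, max(0, brute(L)), tolerance = 1e-6)
  set.seed(9)
  for (r in 1:30) {
    L <- rnorm(sample(3:12, 1), 0, 1.5)
    h <- hlod(L)
    expect_equal(h$hlod, max(0, brute(L)), tolerance = 1e-6)
    expect_gte(h$hlod, 0)
    expect_gte(h$hlod, sum(L) - 1e-9)   # alpha = 1 value
  }
})

test_that("driving families are exactly those with lod above 0.2", {
  lods <- data.frame(family_id = letters[1:5],
                     lod = c(0.19, 0.2, 0.21, 1.5, -0.3))
  h <- hlod(lods)
  expect_equal(sort(h$driving_families), c("c", "d"))
})

test_that("single-variant score test is calibrated and powered", {
  set.seed(10)
  n <- 400
  x <- rbinom(n, 2, 0.3)
  # null calibration: permuted phenotype p-values are uniform
  p <- replicate(400, single_variant_association(rnorm(n), x)$min_p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # positive control: a common variant with a real effect
  y <- 0.5 * x + rnorm(n)
  expect_lt(single_variant_association(y, x)$min_p, 1e-6)
  # monomorphic variant undefined
  expect_true(is.na(single_variant_association(y, rep(1, n))$min_p))
})

test_that("joint linkage decomposes into per-family contributions", {
  cfg <- raredrop_config(n_linked = 8, n_null = 6, seed = 4)
  d <- run_raredrop_demo(cfg)
  expect_equal(sum(d$lods$lod), d$joint_lod, tolerance = 1e-8)
  expect_true(any(d$lods$lod < 0) || all(d$lods$lod == 0))
})
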