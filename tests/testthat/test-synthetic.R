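test_that("M-value/beta transforms are mutually inverse with known fixed points", {
  expect_equal(mToBeta(0), 0.5)
  expect_equal(mToBeta(1), 2 / 3)
  x <- c(-5, -1, 0, 1, 5)
  expect_equal(betaToM(mToBeta(x)), x)
  b <- c(0.01, 0.3, 0.5, 0.9, 0.999)
  expect_equal(mToBeta(betaToM(b)), b)
  expect_true(all(diff(mToBeta(seq(-10, 10, by = 0.5))) > 0))
  expect_error(betaToM(1))
  expect_error(mToBeta(Inf))
})

test_that("config validation rejects invalid counts, MAFs and boundary-pushing effects", {
  expect_error(simulationConfig(n_cases = 0), "counts")
  expect_error(simulationConfig(maf_range = c(0.3, 0.1)), "mafRange")
  expect_error(simulationConfig(maf_range = c(0.1, 0.6)), "mafRange")
  expect_error(simulationConfig(ld_rho = 1), "ldRho")
  expect_error(
    simulationConfig(planted_axes = plantedAxis(50, 1, 1)), "indices")
  # effects that push expected beta to the boundary of (0,1) are rejected
  expect_error(
    simulationConfig(planted_axes = plantedAxis(1, 1, 1, meqtl_beta = 15,
                                                tumor_meth_shift = 10)),
    "boundary")
})

test_that("empirical MAF matches the configured frequency within 3 standard errors", {
  cfg <- simulationConfig(n_cases = 2500, n_controls = 2500,
                          n_normal_tissue = 2, n_tumor_tissue = 2,
                          n_snps = 1, n_cpgs = 2, n_genes = 2,
                          maf_range = c(0.158, 0.158), seed = 101)
  co <- simulateCohort(cfg)
  n <- nrow(genotypes(co))
  f <- mean(genotypes(co)[, 1]) / 2
  se <- sqrt(0.158 * (1 - 0.158) / (2 * n))
  expect_lt(abs(f - 0.158), 3 * se)
})

test_that("genotypes satisfy Hardy-Weinberg proportions at the configured MAF", {
  pass <- vapply(1:20, function(s) {
    cfg <- simulationConfig(n_cases = 2500, n_controls = 2500,
                            n_normal_tissue = 2, n_tumor_tissue = 2,
                            n_snps = 5, n_cpgs = 2, n_genes = 2,
                            maf_range = c(0.1, 0.4), seed = 1000 + s)
    hap <- simulateHaplotypes(cfg)
    g <- hap$hap1 + hap$hap2
    ps <- vapply(seq_len(ncol(g)), function(j) {
      q <- hap$maf[j]
      obs <- tabulate(g[, j] + 1L, nbins = 3L)
      stats::chisq.test(obs, p = c((1 - q)^2, 2 * q * (1 - q), q^2))$p.value
    }, numeric(1))
    all(ps > 0.001)
  }, logical(1))
  expect_gte(sum(pass), 19L)
})

test_that("AR(1) haplotype copier produces the intended pairwise LD", {
  cfg <- simulationConfig(n_cases = 1000, n_controls = 1000,
                          n_normal_tissue = 2, n_tumor_tissue = 2,
                          n_snps = 2, n_cpgs = 2, n_genes = 2,
                          maf_range = c(0.3, 0.3), ld_block_size = 2,
                          ld_rho = 0.95, seed = 77)
  hap <- simulateHaplotypes(cfg)
  dosage <- hap$hap1 + hap$hap2
  # brute-force r2 from the haplotype table, before dosage collapse
  alleleR2 <- r2Oracle(c(hap$hap1[, 1], hap$hap2[, 1]),
                       c(hap$hap1[, 2], hap$hap2[, 2]))
  expect_gt(alleleR2, 0.8)
  expect_gt(ldR2(dosage[, 1], dosage[, 2]), 0.8)
  # and the cohort's genotype matrix is exactly the haplotype collapse
  co <- simulateCohort(cfg)
  expect_identical(unname(genotypes(co)),
                   unname(hap$hap1 + hap$hap2))
})

test_that("null per-allele effect leaves case/control MAFs compatible", {
  zs <- vapply(1:20, function(s) {
    cfg <- simulationConfig(n_cases = 500, n_controls = 500,
                            n_normal_tissue = 2, n_tumor_tissue = 2,
                            n_snps = 1, n_cpgs = 2, n_genes = 2,
                            maf_range = c(0.3, 0.3),
                            planted_axes = plantedAxis(1, 1, 1,
                              per_allele_log_or = 0),
                            seed = 2000 + s)
    co <- associationCohort(simulateCohort(cfg))
    st <- phenotype(co)$status
    fc <- mean(genotypes(co)[st == "case", 1]) / 2
    fn <- mean(genotypes(co)[st == "control", 1]) / 2
    nca <- sum(st == "case"); nco <- sum(st == "control")
    fb <- (fc * nca + fn * nco) / (nca + nco)
    (fc - fn) / sqrt(fb * (1 - fb) * (1 / (2 * nca) + 1 / (2 * nco)))
  }, numeric(1))
  expect_true(all(abs(zs) < 4))
})

test_that("a planted negative methylation-expression slope yields negative tumor correlation", {
  rs <- vapply(1:10, function(s) {
    cfg <- simulationConfig(n_cases = 2, n_controls = 2,
                            n_normal_tissue = 2, n_tumor_tissue = 500,
                            n_snps = 1, n_cpgs = 2, n_genes = 2,
                            planted_axes = plantedAxis(1, 1, 1,
                              meth_expr_slope = -1),
                            noise_sd_m = 1, noise_sd_expr = 1,
                            baseline_expr = 8, seed = 3000 + s)
    tis <- tissuePanel(simulateCohort(cfg))
    tum <- phenotype(tis)$tissue == "tumor"
    cor(betaToM(methylation(tis)[tum, 1]), exprValues(tis)[tum, 1])
  }, numeric(1))
  expect_true(all(rs < 0))
})

test_that("expected case fraction tracks the configured cohort composition", {
  cfg <- simulationConfig(n_cases = 3453, n_controls = 3710,
                          n_normal_tissue = 2, n_tumor_tissue = 2,
                          n_snps = 1, n_cpgs = 2, n_genes = 2,
                          maf_range = c(0.158, 0.158),
                          planted_axes = plantedAxis(1, 1, 1,
                            per_allele_log_or = log(0.89)),
                          seed = 55)
  co <- associationCohort(simulateCohort(cfg))
  frac <- mean(phenotype(co)$status == "case")
  target <- 3453 / (3453 + 3710)
  expect_lt(abs(frac - target), 3 * sqrt(target * (1 - target) / 7163))
})

test_that("identical seeds give byte-identical cohort directories", {
  cfg <- plantedTrioConfig(seed = 9, n_tumor = 30, n_normal = 20,
                           n_bg_cpgs = 20)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  writeCohort(simulateCohort(cfg), d1)
  writeCohort(simulateCohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
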