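refMeqtl <- function() {
  # two-source record table around the strongest published pair plus fillers
  data.frame(
    snp_id = rep(c("rs939408", "rs0001", "rs0002"), each = 2),
    cpg_id = rep(c("cg09596674", "cgA", "cgB"), each = 2),
    beta_sign = c("-", "-", "+", "-", "+", "+"),
    p_value = c(1.75e-5, 6.89e-8, 0.9, 0.8, 0.7, 0.95),
    source = rep(c("tissue", "blood"), 3))
}

test_that("meQTL intersection keeps consensus pairs passing FDR in both sources", {
  cons <- data.frame(cpg_id = c("cg09596674", "cgA"),
                     direction = c("Hyper", "Hyper"))
  got <- intersectMeqtl(cons, refMeqtl())
  expect_equal(got$snp_id, "rs939408")
  expect_equal(got$beta_sign_tissue, "-")
  expect_equal(got$beta_sign_blood, "-")
  expect_equal(got$meqtl_p_tissue, 1.75e-5)
  expect_equal(got$meqtl_p_blood, 6.89e-8)
})

test_that("sign-discordant pairs are excluded by default but kept when allowed", {
  cons <- data.frame(cpg_id = "cgX")
  meqtl <- data.frame(snp_id = "rsX", cpg_id = "cgX",
                      beta_sign = c("+", "-"), p_value = 1e-8,
                      source = c("tissue", "blood"))
  expect_equal(nrow(intersectMeqtl(cons, meqtl)), 0L)
  expect_equal(nrow(intersectMeqtl(cons, meqtl,
                                   require_sign_agreement = FALSE)), 1L)
})

test_that("intersection output is a subset of the consensus CpG set", {
  set.seed(71)
  meqtl <- data.frame(snp_id = rep(paste0("rs", 1:5), 2),
                      cpg_id = rep(paste0("cg", 1:5), 2),
                      beta_sign = "+",
                      p_value = runif(10, 0, 1e-4),
                      source = rep(c("tissue", "blood"), each = 5))
  cons <- data.frame(cpg_id = paste0("cg", c(1, 3, 5)))
  got <- intersectMeqtl(cons, meqtl)
  expect_true(all(got$cpg_id %in% cons$cpg_id))
  # a pair present in a single source is excluded and counted
  one <- rbind(meqtl, data.frame(snp_id = "rs9", cpg_id = "cg1",
                                 beta_sign = "+", p_value = 1e-9,
                                 source = "tissue"))
  got2 <- intersectMeqtl(cons, one)
  expect_false("rs9" %in% got2$snp_id)
  expect_equal(attr(got2, "single_source"), 1L)
})

test_that("correlation filter keeps strong signed correlations and enforces strict cutoffs", {
  set.seed(72)
  n <- 455
  m <- mToBeta(rnorm(n, 0, 1))
  geneNeg <- pmax(10 - 2 * betaToM(m) + rnorm(n, 0, 0.5), 0)
  meth <- cbind(cpgNeg = m, cpgSelf = m)
  expr <- cbind(geneNeg = geneNeg, geneSelf = 2^betaToM(m) - 1)
  rownames(meth) <- rownames(expr) <- paste0("s", 1:n)
  map <- data.frame(cpg_id = c("cpgNeg", "cpgSelf"),
                    gene_symbol = c("geneNeg", "geneSelf"))
  pairs <- data.frame(snp_id = c("rs1", "rs2"),
                      cpg_id = c("cpgNeg", "cpgSelf"))
  got <- correlationFilter(meth, expr, pairs, map)
  neg <- got[got$cpg_id == "cpgNeg", ]
  expect_lt(neg$correlation_r, -0.3)
  # log2(expr+1) of geneSelf is exactly the CpG M-value: r = 1
  expect_equal(got[got$cpg_id == "cpgSelf", "correlation_r"], 1)
})

test_that("correlation threshold is strict and constant vectors are dropped", {
  set.seed(73)
  n <- 1000
  x <- rnorm(n)
  # construct sample correlation exactly 0.29: strong p but below the cutoff
  xs <- as.numeric(scale(x))
  ep <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))
  y <- 0.29 * xs + sqrt(1 - 0.29^2) * ep
  r <- cor(x, y)
  expect_equal(abs(r), 0.29)
  expect_lt(cor.test(x, y)$p.value, 0.01)
  meth <- cbind(cpg1 = mToBeta(x))
  expr <- cbind(g1 = y - min(y))
  rownames(meth) <- rownames(expr) <- paste0("s", 1:n)
  map <- data.frame(cpg_id = "cpg1", gene_symbol = "g1")
  pairs <- data.frame(snp_id = "rs1", cpg_id = "cpg1")
  got <- correlationFilter(meth, expr, pairs, map)
  expect_equal(nrow(got), 0L)
  exprConst <- cbind(g1 = rep(2, n))
  rownames(exprConst) <- rownames(meth)
  expect_warning(got2 <- correlationFilter(meth, exprConst, pairs, map),
                 "constant")
  expect_equal(nrow(got2), 0L)
})

test_that("expression filter applies the fold-change window and FDR", {
  set.seed(74)
  n <- 40
  tissue <- rep(c("tumor", "normal"), each = n / 2)
  mk <- function(mt, mn) c(rnorm(n / 2, mt, 0.5), rnorm(n / 2, mn, 0.5))
  expr <- cbind(gDown = mk(10, 40), gMid = mk(18, 10), gFlat = mk(20, 20))
  rownames(expr) <- paste0("s", 1:n)
  got <- expressionFilter(expr, tissue, c("gDown", "gMid", "gFlat"))
  expect_equal(got$gene_symbol, "gDown")
  expect_lt(abs(got$fold_change - 0.25), 0.05)
  expect_equal(got$direction, "Low")
  tested <- attr(got, "tested")
  # FC ~ 1.8 sits inside the excluded window whatever its p-value
  expect_false("gMid" %in% got$gene_symbol)
  expect_lt(tested[tested$gene_symbol == "gMid", "p_fdr"], 0.05)
})

test_that("planted low-expression genes are recovered across seeds", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulationConfig(n_cases = 2, n_controls = 2,
                            n_normal_tissue = 50, n_tumor_tissue = 50,
                            n_snps = 1, n_cpgs = 5, n_genes = 20,
                            planted_axes = plantedAxis(1, 1, 1,
                              tumor_meth_shift = 2, meth_expr_slope = -1),
                            baseline_expr = 2, noise_sd_m = 0.5,
                            seed = 7000 + s)
    tis <- tissuePanel(simulateCohort(cfg))
    got <- expressionFilter(exprValues(tis), phenotype(tis)$tissue,
                            colnames(exprValues(tis)))
    "gene001" %in% got$gene_symbol[got$direction == "Low"]
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("dosage r2 matches its definition and is allele-flip invariant", {
  set.seed(75)
  a <- rbinom(50, 2, 0.4)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2 - a), 1)
  for (i in 1:100) {
    x <- rbinom(30, 2, runif(1, 0.1, 0.5)) + 0
    y <- pmin(pmax(x + rbinom(30, 1, 0.3) - rbinom(30, 1, 0.3), 0), 2)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(ldR2(x, y), r2Oracle(x, y))
  }
  expect_error(ldR2(rep(1, 10), a[1:10], ids = c("rsZ", "rsA")), "rsZ")
})

test_that("independent SNPs show near-zero r2", {
  small <- vapply(1:20, function(s) {
    set.seed(7100 + s)
    ldR2(rbinom(2000, 2, 0.3), rbinom(2000, 2, 0.3))
  }, numeric(1))
  expect_gte(sum(small < 0.01), 18L)
})

test_that("LD pruning keeps the smallest-p representative and gates on MAF", {
  set.seed(76)
  g1 <- rbinom(200, 2, 0.3)
  panel <- cbind(rsA = g1, rsB = g1, rsRare = rbinom(200, 1, 0.04))
  cand <- data.frame(snp_id = c("rsA", "rsB", "rsRare"),
                     meqtl_p_tissue = c(1e-4, 1e-8, 1e-9))
  got <- ldPrune(cand, panel)
  expect_equal(got$snp_id, "rsB")            # perfectly correlated: keep 1e-8
  expect_true("rsA" %in% attr(got, "dropped_ld"))
  expect_true("rsRare" %in% attr(got, "dropped_maf"))
  # missing SNPs are reported, not fatal
  cand2 <- rbind(cand, data.frame(snp_id = "rsGone", meqtl_p_tissue = 1e-10))
  got2 <- ldPrune(cand2, panel)
  expect_equal(attr(got2, "missing_snps"), "rsGone")
})

test_that("pruned sets are pairwise below the r2 cutoff and greedily maximal", {
  cfg <- simulationConfig(n_cases = 500, n_controls = 500,
                          n_normal_tissue = 2, n_tumor_tissue = 2,
                          n_snps = 50, n_cpgs = 2, n_genes = 2,
                          maf_range = c(0.1, 0.45), ld_block_size = 5,
                          ld_rho = 0.92, seed = 78)
  panel <- genotypes(simulateCohort(cfg))
  set.seed(79)
  cand <- data.frame(snp_id = colnames(panel),
                     meqtl_p_tissue = runif(50, 1e-10, 1e-2))
  got <- ldPrune(cand, panel)
  kept <- unique(got$snp_id)
  for (i in seq_along(kept)) for (j in seq_len(i - 1L))
    expect_lt(r2Oracle(panel[, kept[i]], panel[, kept[j]]), 0.8)
  for (s in attr(got, "dropped_ld"))
    expect_true(any(vapply(kept, function(k)
      r2Oracle(panel[, s], panel[, k]) >= 0.8, logical(1))))
  # invariant under sample relabeling of the reference panel
  perm <- sample(nrow(panel))
  expect_equal(ldPrune(cand, panel[perm, ])$snp_id, got$snp_id)
})

test_that("the funnel recovers planted axes and reports non-increasing counts", {
  cfg <- plantedTrioConfig(seed = 301)
  res <- runPlantedFunnel(cfg)
  expect_setequal(res$candidates$snp_id, c("snp0001", "snp0004", "snp0007"))
  expect_setequal(res$candidates$cpg_id, c("cpg0001", "cpg0002", "cpg0003"))
  expect_setequal(res$candidates$gene_symbol,
                  c("gene001", "gene002", "gene003"))
  expect_true(all(res$report$items_out <= res$report$items_in))
  expect_equal(res$report$items_in[-1], res$report$items_out[-nrow(res$report)])
  expect_true(all(res$candidates$correlation_r < -0.3))
  expect_true(all(res$candidates$expr_fold_change < 0.5))
})

test_that("an empty consensus set flows through as an empty funnel", {
  cfg <- plantedTrioConfig(seed = 302, n_tumor = 20, n_normal = 20,
                           n_bg_cpgs = 10)
  tis <- tissuePanel(simulateCohort(cfg))
  cons <- data.frame(cpg_id = character(0), direction = character(0))
  res <- runFunnel(cons, plantedMeqtlTable(cfg, n_null = 10),
                   methylation(tis), exprValues(tis), phenotype(tis)$tissue,
                   cpgAnnotation(tis), genotypes(tis))
  expect_equal(nrow(res$candidates), 0L)
  expect_true(all(res$report$items_out[-1] == 0L))
})

test_that("disabled thresholds let every intersected pair through", {
  cfg <- plantedTrioConfig(seed = 303, n_tumor = 60, n_normal = 40,
                           n_bg_cpgs = 50)
  tis <- tissuePanel(simulateCohort(cfg))
  dm <- testDifferentialMethylation(methylation(tis), phenotype(tis)$tissue)
  cons <- consensusSites(dm, dm)
  meqtl <- plantedMeqtlTable(cfg, n_null = 30)
  open <- funnelThresholds(meqtl_fdr = 1.01, require_sign_agreement = FALSE,
                           r = -1, r_p = 1.01, fc_low = 1, fc_high = 1,
                           expr_fdr = 1.01, maf = -1, ld_r2 = 1.01)
  res <- suppressWarnings(
    runFunnel(cons, meqtl, methylation(tis), exprValues(tis),
              phenotype(tis)$tissue, cpgAnnotation(tis), genotypes(tis),
              open))
  inter <- intersectMeqtl(cons, meqtl, 1.01, FALSE)
  expect_equal(nrow(res$candidates), nrow(inter))
})

test_that("tightening any single threshold never enlarges the surviving set", {
  cfg <- plantedTrioConfig(seed = 304, n_tumor = 100, n_normal = 40,
                           n_bg_cpgs = 200)
  tis <- tissuePanel(simulateCohort(cfg))
  dm <- testDifferentialMethylation(methylation(tis), phenotype(tis)$tissue)
  cons <- consensusSites(dm, dm)
  meqtl <- plantedMeqtlTable(cfg, n_null = 50)
  run <- function(th) suppressWarnings(
    runFunnel(cons, meqtl, methylation(tis), exprValues(tis),
              phenotype(tis)$tissue, cpgAnnotation(tis), genotypes(tis), th))
  key <- function(res) paste(res$candidates$snp_id, res$candidates$cpg_id)
  base <- key(run(funnelThresholds()))
  tighter <- list(funnelThresholds(meqtl_fdr = 0.01),
                  funnelThresholds(r = 0.6),
                  funnelThresholds(fc_low = 0.2, fc_high = 5),
                  funnelThresholds(expr_fdr = 0.001),
                  funnelThresholds(maf = 0.25),
                  funnelThresholds(ld_r2 = 0.1))
  for (th in tighter)
    expect_true(all(key(run(th)) %in% base))
})
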