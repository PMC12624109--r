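# Shared simulation set-ups used across test files.

# Three concordant negative-regulation axes in separate LD blocks, strong
# enough that every funnel stage has essentially full power at the default
# tissue-panel size (500 tumor / 50 normal).
plantedTrioConfig <- function(seed, n_tumor = 500, n_normal = 50,
                              n_bg_cpgs = 2000, log_or = log(0.8)) {
  ax <- plantedAxis(snp_index = c(1L, 4L, 7L), cpg_index = c(1L, 2L, 3L),
                    gene_index = c(1L, 2L, 3L),
                    meqtl_beta = c(1, -1, 1), tumor_meth_shift = 2,
                    meth_expr_slope = -3, per_allele_log_or = log_or)
  simulationConfig(n_cases = 10, n_controls = 10,
                   n_normal_tissue = n_normal, n_tumor_tissue = n_tumor,
                   n_snps = 9, n_cpgs = 3L + n_bg_cpgs, n_genes = 100,
                   maf_range = c(0.2, 0.4), ld_block_size = 3, ld_rho = 0.3,
                   planted_axes = ax, baseline_expr = 4, noise_sd_m = 0.5,
                   seed = seed)
}

# Simulate two independent tissue panels and run consensus + funnel;
# returns the surviving candidates (and the report).
runPlantedFunnel <- function(cfg, n_null_meqtl = 200) {
  tisA <- tissuePanel(simulateCohort(cfg))
  cfgB <- cfg
  cfgB@seed <- cfg@seed + 100000L
  tisB <- tissuePanel(simulateCohort(cfgB))
  dmA <- testDifferentialMethylation(methylation(tisA), phenotype(tisA)$tissue)
  dmB <- testDifferentialMethylation(methylation(tisB), phenotype(tisB)$tissue)
  cons <- suppressWarnings(consensusSites(dmA, dmB))
  meqtl <- plantedMeqtlTable(cfg, n_null = n_null_meqtl)
  suppressWarnings(runFunnel(cons, meqtl, methylation(tisA),
                             exprValues(tisA), phenotype(tisA)$tissue,
                             cpgAnnotation(tisA), genotypes(tisA)))
}

# Island of 13 CpGs on one gene: the anchor (CpG 1) plus six co-shifted
# partners are hypermethylated in tumor; six are not.
islandConfig <- function(seed, shift = 2, n_tumor = 60, n_normal = 60) {
  ax <- plantedAxis(snp_index = 1L, cpg_index = 1:7, gene_index = 1L,
                    meqtl_beta = 0, tumor_meth_shift = shift,
                    meth_expr_slope = c(-1, rep(0, 6)), per_allele_log_or = 0)
  simulationConfig(n_cases = 2, n_controls = 2,
                   n_normal_tissue = n_normal, n_tumor_tissue = n_tumor,
                   n_snps = 1, n_cpgs = 13, n_genes = 1,
                   planted_axes = ax, noise_sd_m = 0.5, baseline_expr = 12,
                   seed = seed)
}
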