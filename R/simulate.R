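#' Convert between methylation beta values and M-values
#'
#' The two standard scales for CpG methylation are linked by the logistic
#' map: \code{beta = 2^m / (2^m + 1)} and \code{m = log2(beta / (1 - beta))}.
#' Effects in the simulator are specified on the (unbounded,
#' variance-stabilized) M-value scale and transported to the beta scale by
#' \code{mToBeta}, which keeps betas strictly inside (0, 1) without clipping.
#'
#' @param m finite numeric vector of M-values
#' @param beta numeric vector with entries strictly in (0, 1)
#' @return \code{mToBeta}: betas in (0, 1); \code{betaToM}: M-values
#' @examples
#' mToBeta(0)            # 0.5
#' mToBeta(1)            # 2/3
#' betaToM(mToBeta(-3))  # -3
#' @export
mToBeta <- function(m) {
  stopifnot(is.numeric(m), all(is.finite(m)))
  stats::plogis(m * log(2))
}

#' @rdname mToBeta
#' @export
betaToM <- function(beta) {
  stopifnot(is.numeric(beta), all(is.finite(beta)), all(beta > 0), all(beta < 1))
  log2(beta / (1 - beta))
}

.snpIds <- function(n) sprintf("snp%04d", seq_len(n))
.cpgIds <- function(n) sprintf("cpg%04d", seq_len(n))
.geneIds <- function(n) sprintf("gene%03d", seq_len(n))

#' Block MAFs and haplotypes for a configuration
#'
#' Draws per-LD-block minor allele frequencies and the two haplotype matrices
#' underlying the genotype dosages. Haplotypes within a block follow a
#' first-order copying process: the allele at SNP j equals the allele at SNP
#' j-1 with probability \code{ldRho} and is otherwise drawn fresh from
#' Bernoulli(MAF). Because all SNPs of a block share one MAF, the copier
#' preserves marginal allele frequencies exactly (hence Hardy-Weinberg
#' genotype proportions) while giving adjacent SNPs allele correlation
#' \code{ldRho} and dosage r-squared \code{ldRho^2}.
#'
#' Exposed so the haplotype table "before dosage collapse" can be inspected
#' directly, e.g. to cross-check LD summaries against the generating process.
#' [simulateCohort()] calls this internally with the same seed, so
#' \code{hap1 + hap2} reproduces the cohort's genotype matrix.
#'
#' @param config a [SimulationConfig-class]
#' @param n_samples number of diploid samples to generate haplotypes for;
#'   defaults to the full cohort + tissue panel size
#' @return list with \code{maf} (per-SNP numeric), \code{hap1} and
#'   \code{hap2} (0/1 matrices, samples x SNPs)
#' @export
simulateHaplotypes <- function(config, n_samples = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(n_samples))
    n_samples <- config@nCases + config@nControls +
      config@nNormalTissue + config@nTumorTissue
  set.seed(config@seed)
  nsnp <- config@nSnps
  block <- ((seq_len(nsnp) - 1L) %/% config@ldBlockSize) + 1L
  blockMaf <- stats::runif(max(block), config@mafRange[1], config@mafRange[2])
  maf <- blockMaf[block]
  drawPanel <- function() {
    h <- matrix(0L, n_samples, nsnp)
    for (j in seq_len(nsnp)) {
      fresh <- stats::rbinom(n_samples, 1L, maf[j])
      if (j > 1L && block[j] == block[j - 1L] && config@ldRho > 0) {
        copy <- stats::runif(n_samples) < config@ldRho
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      } else {
        h[, j] <- fresh
      }
    }
    h
  }
  list(maf = maf, hap1 = drawPanel(), hap2 = drawPanel())
}

#' Simulate a multi-omic cohort with planted SNP-CpG-gene axes
#'
#' Generates one [MeqtlCohort-class] with the statistical structure the
#' downstream pipeline assumes:
#' \itemize{
#'   \item Genotypes: Hardy-Weinberg dosages from two independent haplotype
#'     panels with autoregressive LD blocks (see [simulateHaplotypes()]).
#'   \item Methylation: each CpG's M-value is
#'     \code{baseline + meqtl_beta * dosage + tumor_meth_shift * is_tumor +
#'     noise}, mapped to the beta scale by [mToBeta()]; non-planted CpGs get
#'     baseline + noise only.
#'   \item Expression: \code{baseline_expr + meth_expr_slope * M + noise},
#'     summed over the planted CpGs of a gene and floored at zero.
#'   \item Phenotype: the tissue panel carries tumor/normal labels; the
#'     association cohort draws case status from
#'     Bernoulli(logistic(b0 + sum(per_allele_log_or * dosage) +
#'     age_log_or * age_std)) with the intercept b0 solved numerically so the
#'     expected case fraction equals \code{n_cases / (n_cases + n_controls)}.
#'     Age is uniform on [40, 75] and standardized before entering the model.
#' }
#' Output is deterministic given \code{config@seed}.
#'
#' @param config a valid [SimulationConfig-class]
#' @return a [MeqtlCohort-class]
#' @examples
#' cfg <- simulationConfig(n_cases = 50, n_controls = 50, seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nCoh <- config@nCases + config@nControls
  nTis <- config@nNormalTissue + config@nTumorTissue
  n <- nCoh + nTis

  hap <- simulateHaplotypes(config, n)  # seeds the RNG stream
  geno <- hap$hap1 + hap$hap2
  storage.mode(geno) <- "integer"

  sampleIds <- sprintf("S%05d", seq_len(n))
  role <- rep(c("cohort", "tissue"), c(nCoh, nTis))
  tissue <- rep(NA_character_, n)
  tissue[role == "tissue"] <- rep(c("normal", "tumor"),
                                  c(config@nNormalTissue, config@nTumorTissue))
  isTumor <- !is.na(tissue) & tissue == "tumor"

  dimnames(geno) <- list(sampleIds, .snpIds(config@nSnps))

  # methylation on the M scale, then logistic map to beta
  m0 <- betaToM(config@baselineBetaMean)
  M <- matrix(stats::rnorm(n * config@nCpgs, m0, config@noiseSdM),
              n, config@nCpgs, dimnames = list(sampleIds, .cpgIds(config@nCpgs)))
  ax <- config@plantedAxes
  for (k in seq_len(nrow(ax))) {
    j <- ax$cpg_index[k]
    M[, j] <- M[, j] + ax$meqtl_beta[k] * geno[, ax$snp_index[k]] +
      ax$tumor_meth_shift[k] * isTumor
  }
  beta <- mToBeta(M)
  if (any(beta <= 0) || any(beta >= 1))
    stop("configuration pushes methylation beta values outside (0, 1)")

  expr <- matrix(stats::rnorm(n * config@nGenes, config@baselineExpr,
                              config@noiseSdExpr),
                 n, config@nGenes,
                 dimnames = list(sampleIds, .geneIds(config@nGenes)))
  for (k in seq_len(nrow(ax)))
    expr[, ax$gene_index[k]] <- expr[, ax$gene_index[k]] +
      ax$meth_expr_slope[k] * M[, ax$cpg_index[k]]
  expr[expr < 0] <- 0

  age <- stats::runif(n, 40, 75)
  ageStd <- (age - 57.5) / (35 / sqrt(12))

  status <- rep(NA_character_, n)
  if (nCoh > 0L) {
    idx <- seq_len(nCoh)
    lp <- ageStd[idx] * config@ageLogOr
    for (k in seq_len(nrow(ax)))
      lp <- lp + ax$per_allele_log_or[k] * geno[idx, ax$snp_index[k]]
    target <- config@nCases / nCoh
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - target,
                         c(-25, 25), tol = 1e-10)$root
    case <- stats::rbinom(nCoh, 1L, stats::plogis(b0 + lp))
    status[idx] <- ifelse(case == 1L, "case", "control")
  }

  pheno <- S4Vectors::DataFrame(role = role, tissue = tissue, status = status,
                                age = age, row.names = sampleIds)

  # default CpG -> gene map is round-robin; planted axes override
  geneOf <- ((seq_len(config@nCpgs) - 1L) %% config@nGenes) + 1L
  geneOf[ax$cpg_index] <- ax$gene_index
  cpgAnn <- data.frame(cpg_id = .cpgIds(config@nCpgs),
                       chromosome = "chr1",
                       position = 10000L + 100L * seq_len(config@nCpgs),
                       gene_symbol = .geneIds(config@nGenes)[geneOf])
  snpAnn <- data.frame(snp_id = .snpIds(config@nSnps),
                       chromosome = "chr1",
                       position = 10050L + 100L * seq_len(config@nSnps),
                       alleles = "A>G",
                       maf = hap$maf)

  new("MeqtlCohort", genotypes = geno, methylation = beta, expression = expr,
      phenotype = pheno, snpAnnotation = snpAnn, cpgAnnotation = cpgAnn)
}

#' Synthetic meQTL summary records matching a configuration's planted axes
#'
#' Builds the tissue- and blood-source meQTL summary table a cohort simulated
#' from \code{config} would be screened against: one record per planted axis
#' and source with the planted effect's sign and a strong p-value, plus
#' \code{n_null} random SNP-CpG pairs per source with uniform p-values and
#' random signs, emulating the bulk of database records that carry no signal
#' relevant to the cohort.
#'
#' @param config a [SimulationConfig-class]
#' @param n_null null records per source
#' @param planted_p p-value assigned to planted records
#' @param seed seed for the null records (independent of the cohort stream)
#' @return data.frame with columns snp_id, cpg_id, beta_sign, p_value, source
#' @export
plantedMeqtlTable <- function(config, n_null = 0, planted_p = 1e-12,
                              seed = config@seed + 1L) {
  stopifnot(is(config, "SimulationConfig"))
  ax <- config@plantedAxes
  snps <- .snpIds(config@nSnps)
  cpgs <- .cpgIds(config@nCpgs)
  rows <- lapply(c("tissue", "blood"), function(src) {
    data.frame(
      snp_id = snps[ax$snp_index], cpg_id = cpgs[ax$cpg_index],
      beta_sign = ifelse(ax$meqtl_beta >= 0, "+", "-"),
      p_value = rep(planted_p, nrow(ax)), source = rep(src, nrow(ax)))
  })
  out <- do.call(rbind, rows)
  if (n_null > 0) {
    set.seed(as.integer(seed))
    nulls <- lapply(c("tissue", "blood"), function(src) {
      data.frame(
        snp_id = sample(snps, n_null, replace = TRUE),
        cpg_id = sample(cpgs, n_null, replace = TRUE),
        beta_sign = sample(c("+", "-"), n_null, replace = TRUE),
        p_value = stats::runif(n_null), source = src)
    })
    out <- rbind(out, do.call(rbind, nulls))
    # keep one record per (snp, cpg, source); planted rows listed first win
    out <- out[!duplicated(out[, c("snp_id", "cpg_id", "source")]), ]
  }
  rownames(out) <- NULL
  out
}
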