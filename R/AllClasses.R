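#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Simulation configuration for synthetic meQTL cohorts
#'
#' An S4 container holding every tunable of the synthetic cohort generator:
#' cohort and tissue-panel sizes, marker counts, the minor-allele-frequency
#' range, the linkage-disequilibrium (LD) block structure, baseline
#' methylation/expression levels, noise standard deviations and the table of
#' planted SNP-CpG-gene axes.
#'
#' Planted axes are rows of the \code{plantedAxes} data.frame with columns
#' \code{snp_index}, \code{cpg_index}, \code{gene_index}, \code{meqtl_beta}
#' (per-allele shift of the CpG on the M-value scale), \code{tumor_meth_shift}
#' (tumor-vs-normal M-value shift), \code{meth_expr_slope} (expression units
#' per M-value unit; negative encodes the negative-regulation model) and
#' \code{per_allele_log_or} (log odds ratio of disease per variant allele).
#'
#' @slot nCases expected number of cases in the case-control cohort
#' @slot nControls expected number of controls
#' @slot nNormalTissue normal samples in the tumor/normal tissue panel
#' @slot nTumorTissue tumor samples in the tissue panel
#' @slot nSnps,nCpgs,nGenes marker/feature counts
#' @slot mafRange length-2 numeric, low/high minor allele frequency in (0, 0.5]
#' @slot ldBlockSize SNPs per LD block
#' @slot ldRho haplotype copying probability in [0, 1); adjacent SNPs in a
#'   block have allele correlation \code{ldRho}, so dosage r-squared
#'   \code{ldRho^2}
#' @slot plantedAxes data.frame of planted axes (see Details)
#' @slot baselineBetaMean baseline methylation beta in (0, 1)
#' @slot noiseSdM per-sample CpG noise standard deviation, M-value scale
#' @slot baselineExpr baseline expression level (linear scale)
#' @slot noiseSdExpr per-sample expression noise standard deviation
#' @slot ageLogOr log odds ratio of disease per standard deviation of age
#' @slot seed integer seed making the cohort reproducible
#'
#' @seealso [simulationConfig()] for the user-facing constructor,
#'   [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nCases = "integer", nControls = "integer",
    nNormalTissue = "integer", nTumorTissue = "integer",
    nSnps = "integer", nCpgs = "integer", nGenes = "integer",
    mafRange = "numeric", ldBlockSize = "integer", ldRho = "numeric",
    plantedAxes = "data.frame",
    baselineBetaMean = "numeric", noiseSdM = "numeric",
    baselineExpr = "numeric", noiseSdExpr = "numeric",
    ageLogOr = "numeric", seed = "integer"
  )
)

.AXIS_COLS <- c("snp_index", "cpg_index", "gene_index", "meqtl_beta",
                "tumor_meth_shift", "meth_expr_slope", "per_allele_log_or")

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  counts <- c(object@nCases, object@nControls, object@nNormalTissue,
              object@nTumorTissue, object@nSnps, object@nCpgs, object@nGenes,
              object@ldBlockSize)
  if (any(is.na(counts)) || any(counts < 1L))
    msg <- c(msg, "all counts must be positive integers")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be (low, high) with 0 < low <= high <= 0.5")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must lie in [0, 1)")
  if (object@baselineBetaMean <= 0 || object@baselineBetaMean >= 1)
    msg <- c(msg, "baselineBetaMean must lie strictly in (0, 1)")
  if (object@noiseSdM <= 0 || object@noiseSdExpr <= 0)
    msg <- c(msg, "noise standard deviations must be positive")
  ax <- object@plantedAxes
  if (!all(.AXIS_COLS %in% names(ax)))
    msg <- c(msg, paste("plantedAxes must have columns:",
                        paste(.AXIS_COLS, collapse = ", ")))
  else if (nrow(ax) > 0L) {
    if (any(ax$snp_index < 1L | ax$snp_index > object@nSnps) ||
        any(ax$cpg_index < 1L | ax$cpg_index > object@nCpgs) ||
        any(ax$gene_index < 1L | ax$gene_index > object@nGenes))
      msg <- c(msg, "planted axis indices must reference valid SNP/CpG/gene positions")
    if (anyDuplicated(ax$cpg_index))
      msg <- c(msg, "each CpG may carry at most one planted axis")
    eff <- ax[, c("meqtl_beta", "tumor_meth_shift", "meth_expr_slope",
                  "per_allele_log_or")]
    if (!all(vapply(eff, function(x) all(is.finite(x)), logical(1))))
      msg <- c(msg, "planted effect sizes must be finite")
    # guard: expected M must keep beta representable inside (0, 1)
    m0 <- log2(object@baselineBetaMean / (1 - object@baselineBetaMean))
    worst <- m0 + abs(ax$meqtl_beta) * 2 + abs(ax$tumor_meth_shift)
    if (any(abs(worst) > 20))
      msg <- c(msg, "planted effects push expected beta values to the boundary of (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Builds a validated [SimulationConfig-class] object. Defaults describe a
#' small but structurally complete cohort; the tissue panel (tumor/normal,
#' used for differential methylation and expression) is generated separately
#' from the case-control association cohort, mirroring the usual split between
#' a tissue discovery population and a GWAS population.
#'
#' @param n_cases,n_controls expected case/control counts of the association
#'   cohort; case status is drawn per sample from a logistic model whose
#'   intercept is solved so the expected case fraction equals
#'   \code{n_cases / (n_cases + n_controls)}
#' @param n_normal_tissue,n_tumor_tissue tissue-panel sizes
#' @param n_snps,n_cpgs,n_genes marker counts
#' @param maf_range length-2 numeric in (0, 0.5]; one MAF is drawn per LD
#'   block, shared by the SNPs of that block
#' @param ld_block_size,ld_rho LD block length and the first-order haplotype
#'   copying probability (adjacent-SNP allele correlation)
#' @param planted_axes data.frame of planted SNP-CpG-gene axes; see
#'   [SimulationConfig-class]
#' @param baseline_beta_mean baseline methylation beta
#' @param noise_sd_m CpG noise sd on the M-value scale
#' @param baseline_expr,noise_sd_expr expression baseline and noise sd
#' @param age_log_or log odds ratio of disease per sd of (standardized) age
#' @param seed integer seed
#' @return a validated \code{SimulationConfig}
#' @examples
#' cfg <- simulationConfig(n_snps = 4, n_cpgs = 4, n_genes = 2,
#'                         planted_axes = plantedAxis(1, 1, 1,
#'                           meqtl_beta = -1, tumor_meth_shift = 2,
#'                           meth_expr_slope = -3, per_allele_log_or = log(0.9)))
#' cfg
#' @export
simulationConfig <- function(n_cases = 100, n_controls = 100,
                             n_normal_tissue = 50, n_tumor_tissue = 50,
                             n_snps = 10, n_cpgs = 20, n_genes = 10,
                             maf_range = c(0.1, 0.4),
                             ld_block_size = 1, ld_rho = 0,
                             planted_axes = emptyPlantedAxes(),
                             baseline_beta_mean = 0.3,
                             noise_sd_m = 0.5,
                             baseline_expr = 8, noise_sd_expr = 1,
                             age_log_or = 0.1,
                             seed = 1L) {
  new("SimulationConfig",
      nCases = as.integer(n_cases), nControls = as.integer(n_controls),
      nNormalTissue = as.integer(n_normal_tissue),
      nTumorTissue = as.integer(n_tumor_tissue),
      nSnps = as.integer(n_snps), nCpgs = as.integer(n_cpgs),
      nGenes = as.integer(n_genes),
      mafRange = as.numeric(maf_range),
      ldBlockSize = as.integer(ld_block_size), ldRho = as.numeric(ld_rho),
      plantedAxes = as.data.frame(planted_axes),
      baselineBetaMean = as.numeric(baseline_beta_mean),
      noiseSdM = as.numeric(noise_sd_m),
      baselineExpr = as.numeric(baseline_expr),
      noiseSdExpr = as.numeric(noise_sd_expr),
      ageLogOr = as.numeric(age_log_or),
      seed = as.integer(seed))
}

#' Describe one or more planted axes
#'
#' Convenience constructor for the \code{planted_axes} slot of a
#' [SimulationConfig-class]. Arguments are recycled to a common length, so a
#' single call can plant several axes. All four effect signs are independently
#' settable, which allows planting both axes that satisfy and axes that
#' violate the negative-regulation plausibility pattern.
#'
#' @param snp_index,cpg_index,gene_index 1-based marker indices
#' @param meqtl_beta per-variant-allele CpG shift, M-value scale
#' @param tumor_meth_shift tumor-vs-normal CpG shift, M-value scale
#' @param meth_expr_slope expression change per M-value unit (negative for
#'   methylation-silenced genes)
#' @param per_allele_log_or log odds ratio of disease per variant allele
#' @return data.frame with one row per axis
#' @export
plantedAxis <- function(snp_index, cpg_index, gene_index,
                        meqtl_beta = 0, tumor_meth_shift = 0,
                        meth_expr_slope = 0, per_allele_log_or = 0) {
  data.frame(snp_index = as.integer(snp_index),
             cpg_index = as.integer(cpg_index),
             gene_index = as.integer(gene_index),
             meqtl_beta = meqtl_beta,
             tumor_meth_shift = tumor_meth_shift,
             meth_expr_slope = meth_expr_slope,
             per_allele_log_or = per_allele_log_or)
}

#' @rdname plantedAxis
#' @export
emptyPlantedAxes <- function() {
  plantedAxis(integer(0), integer(0), integer(0), numeric(0), numeric(0),
              numeric(0), numeric(0))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohort: %d cases / %d controls (expected); tissue panel: %d tumor / %d normal\n",
              object@nCases, object@nControls,
              object@nTumorTissue, object@nNormalTissue))
  cat(sprintf("  markers: %d SNPs (blocks of %d, rho = %.2f, MAF %.3f-%.3f), %d CpGs, %d genes\n",
              object@nSnps, object@ldBlockSize, object@ldRho,
              object@mafRange[1], object@mafRange[2],
              object@nCpgs, object@nGenes))
  cat(sprintf("  planted axes: %d; seed: %d\n",
              nrow(object@plantedAxes), object@seed))
})

#' Aligned multi-omic cohort container
#'
#' Holds the four row-aligned components of one synthetic or imported cohort:
#' a samples-by-SNPs genotype dosage matrix (entries 0/1/2 counting the
#' variant allele), a samples-by-CpGs methylation beta matrix (entries
#' strictly inside (0, 1)), a samples-by-genes nonnegative expression matrix,
#' and a per-sample phenotype \code{DataFrame} with columns \code{role}
#' ("cohort" for association samples, "tissue" for the tumor/normal panel),
#' \code{tissue} ("tumor"/"normal", NA for cohort samples), \code{status}
#' ("case"/"control", NA for tissue samples) and \code{age} (years).
#'
#' @slot genotypes samples x SNPs integer dosage matrix
#' @slot methylation samples x CpGs beta-value matrix
#' @slot expression samples x genes expression matrix
#' @slot phenotype S4Vectors DataFrame, one row per sample
#' @slot snpAnnotation data.frame: snp_id, chromosome, position, alleles
#' @slot cpgAnnotation data.frame: cpg_id, chromosome, position, gene_symbol
#'
#' @seealso [simulateCohort()], [genotypes()], [methylation()],
#'   [exprValues()], [phenotype()]
#' @export
setClass("MeqtlCohort",
  representation(
    genotypes = "matrix", methylation = "matrix", expression = "matrix",
    phenotype = "DataFrame",
    snpAnnotation = "data.frame", cpgAnnotation = "data.frame"
  )
)

setValidity("MeqtlCohort", function(object) {
  msg <- character(0)
  n <- nrow(object@genotypes)
  if (nrow(object@methylation) != n || nrow(object@expression) != n ||
      nrow(object@phenotype) != n)
    msg <- c(msg, "genotype, methylation, expression and phenotype row counts must agree")
  if (!identical(rownames(object@genotypes), rownames(object@methylation)) ||
      !identical(rownames(object@genotypes), rownames(object@expression)))
    msg <- c(msg, "sample IDs must be identical across matrices")
  g <- object@genotypes
  if (length(g) && (any(g != round(g)) || any(g < 0 | g > 2)))
    msg <- c(msg, "genotype dosages must be integers in {0, 1, 2}")
  b <- object@methylation
  if (length(b) && (any(b <= 0) || any(b >= 1)))
    msg <- c(msg, "methylation beta values must lie strictly in (0, 1)")
  if (length(object@expression) && any(object@expression < 0))
    msg <- c(msg, "expression values must be nonnegative")
  need <- c("role", "tissue", "status", "age")
  if (!all(need %in% colnames(object@phenotype)))
    msg <- c(msg, paste("phenotype must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "MeqtlCohort", function(object) {
  ph <- object@phenotype
  cat("MeqtlCohort\n")
  cat(sprintf("  %d samples: %d cases / %d controls, %d tumor / %d normal tissue\n",
              nrow(ph),
              sum(ph$status == "case", na.rm = TRUE),
              sum(ph$status == "control", na.rm = TRUE),
              sum(ph$tissue == "tumor", na.rm = TRUE),
              sum(ph$tissue == "normal", na.rm = TRUE)))
  cat(sprintf("  %d SNPs, %d CpGs, %d genes\n",
              ncol(object@genotypes), ncol(object@methylation),
              ncol(object@expression)))
})
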