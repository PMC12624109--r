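## Stages 2-5 of the discovery funnel: meQTL intersection, methylation-
## expression correlation, differential expression, MAF gate and LD pruning.

#' Default funnel thresholds
#'
#' All cutoffs are strict inequalities: meQTL FDR < 0.05 in both sources,
#' |r| > 0.3 with p < 0.05 for the methylation-expression correlation,
#' fold change > 2 or < 0.5 with FDR < 0.05 for differential expression,
#' reference MAF > 0.05, and pairwise LD r-squared < 0.80 after pruning.
#'
#' @param meqtl_fdr per-source meQTL FDR cutoff
#' @param require_sign_agreement require the meQTL effect sign to agree
#'   between the tissue and blood sources (default on; the bundled
#'   seven-axis reference table satisfies it for every axis)
#' @param r,r_p correlation-filter cutoffs (absolute r, p-value)
#' @param fc_low,fc_high fold-change window excluded as "not changed"
#' @param expr_fdr differential-expression FDR cutoff
#' @param maf reference minor-allele-frequency gate
#' @param ld_r2 pairwise r-squared above which SNPs are considered redundant
#' @param correlation_samples "tumor" (default) or "all": samples used for
#'   the methylation-expression correlation
#' @return named list of thresholds for [runFunnel()]
#' @export
funnelThresholds <- function(meqtl_fdr = 0.05, require_sign_agreement = TRUE,
                             r = 0.3, r_p = 0.05,
                             fc_low = 0.5, fc_high = 2.0, expr_fdr = 0.05,
                             maf = 0.05, ld_r2 = 0.8,
                             correlation_samples = c("tumor", "all")) {
  list(meqtl_fdr = meqtl_fdr,
       require_sign_agreement = isTRUE(require_sign_agreement),
       r = r, r_p = r_p, fc_low = fc_low, fc_high = fc_high,
       expr_fdr = expr_fdr, maf = maf, ld_r2 = ld_r2,
       correlation_samples = match.arg(correlation_samples))
}

#' Intersect consensus CpGs with tissue and blood meQTL records
#'
#' Keeps SNP-CpG pairs whose CpG is in the consensus differentially
#' methylated set and whose meQTL record passes Benjamini-Hochberg FDR
#' (computed within each source over all of that source's records) in BOTH
#' the tissue and the blood source. By default the meQTL effect sign must
#' also agree between sources. Pairs present in only one source are excluded
#' and counted in \code{attr(, "single_source")}.
#'
#' @param consensus data.frame from [consensusSites()] (or any table with a
#'   \code{cpg_id} column)
#' @param meqtl data.frame with columns snp_id, cpg_id, beta_sign ("+"/"-"),
#'   p_value, source ("tissue"/"blood"); one record per (snp, cpg, source)
#' @param fdr_threshold per-source FDR cutoff (strict)
#' @param require_sign_agreement drop pairs whose signs disagree across
#'   sources
#' @return data.frame: snp_id, cpg_id, beta_sign_tissue, beta_sign_blood,
#'   meqtl_p_tissue, meqtl_p_blood, meqtl_fdr_tissue, meqtl_fdr_blood
#' @export
intersectMeqtl <- function(consensus, meqtl, fdr_threshold = 0.05,
                           require_sign_agreement = TRUE) {
  need <- c("snp_id", "cpg_id", "beta_sign", "p_value", "source")
  stopifnot(all(need %in% names(meqtl)),
            all(meqtl$source %in% c("tissue", "blood")),
            all(meqtl$beta_sign %in% c("+", "-")))
  if (anyDuplicated(meqtl[, c("snp_id", "cpg_id", "source")]))
    stop("meqtl table must have one record per (snp, cpg, source)")
  if (!all(c("tissue", "blood") %in% meqtl$source))
    stop("records from both the tissue and blood source are required")
  meqtl$p_fdr <- stats::ave(meqtl$p_value, meqtl$source,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  tis <- meqtl[meqtl$source == "tissue", ]
  blo <- meqtl[meqtl$source == "blood", ]
  m <- merge(tis, blo, by = c("snp_id", "cpg_id"),
             suffixes = c("_tissue", "_blood"))
  nSingle <- nrow(tis) + nrow(blo) - 2L * nrow(m)
  keep <- m$cpg_id %in% consensus$cpg_id &
    m$p_fdr_tissue < fdr_threshold & m$p_fdr_blood < fdr_threshold
  if (require_sign_agreement)
    keep <- keep & m$beta_sign_tissue == m$beta_sign_blood
  out <- data.frame(snp_id = m$snp_id[keep], cpg_id = m$cpg_id[keep],
                    beta_sign_tissue = m$beta_sign_tissue[keep],
                    beta_sign_blood = m$beta_sign_blood[keep],
                    meqtl_p_tissue = m$p_value_tissue[keep],
                    meqtl_p_blood = m$p_value_blood[keep],
                    meqtl_fdr_tissue = m$p_fdr_tissue[keep],
                    meqtl_fdr_blood = m$p_fdr_blood[keep])
  out <- out[order(out$snp_id, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "single_source") <- nSingle
  out
}

#' Methylation-expression correlation filter
#'
#' For each SNP-CpG pair, computes the Pearson correlation between the CpG's
#' M-values and log2(expression + 1) of its mapped gene across the supplied
#' samples (tumor samples only under the default funnel configuration), and
#' keeps pairs with \code{|r| > r_threshold} and \code{p < p_threshold}
#' (both strict). The signed r is recorded. Pairs whose gene is absent from
#' the expression matrix or whose expression vector is constant are dropped
#' with a warning.
#'
#' @param meth samples x CpGs beta matrix
#' @param expr samples x genes expression matrix (same samples, same order)
#' @param pairs data.frame with at least snp_id and cpg_id (e.g. from
#'   [intersectMeqtl()])
#' @param cpg_gene data.frame mapping cpg_id to gene_symbol
#' @param r_threshold,p_threshold strict cutoffs
#' @return \code{pairs} rows that survive, with gene_symbol, correlation_r
#'   and correlation_p appended
#' @export
correlationFilter <- function(meth, expr, pairs, cpg_gene,
                              r_threshold = 0.3, p_threshold = 0.05) {
  stopifnot(nrow(meth) == nrow(expr),
            all(c("cpg_id", "gene_symbol") %in% names(cpg_gene)))
  pairs$gene_symbol <- cpg_gene$gene_symbol[match(pairs$cpg_id, cpg_gene$cpg_id)]
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cpg <- pairs$cpg_id[i]; gene <- pairs$gene_symbol[i]
    if (is.na(gene) || !gene %in% colnames(expr) || !cpg %in% colnames(meth)) {
      warning("pair ", pairs$snp_id[i], "-", cpg,
              ": gene or CpG not present in the matrices; dropped")
      next
    }
    x <- betaToM(meth[, cpg])
    y <- log2(expr[, gene] + 1)
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      warning("pair ", pairs$snp_id[i], "-", cpg,
              ": constant methylation or expression vector; dropped")
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  pairs$correlation_r <- r
  pairs$correlation_p <- p
  keep <- !is.na(r) & abs(r) > r_threshold & p < p_threshold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor-vs-normal differential expression filter
#'
#' Fold change is the ratio of linear-scale group means,
#' \code{mean(tumor) / mean(normal)}; the test is Welch's t on
#' log2(expression + 1), with Benjamini-Hochberg adjustment across the
#' tested genes. Genes are kept when \code{FC > fc_high} or
#' \code{FC < fc_low} and \code{p_fdr < fdr_threshold} (all strict).
#' Direction is "High" iff FC > 1. Genes with a zero normal-group mean have
#' an undefined fold change and are dropped with a warning.
#'
#' @param expr samples x genes expression matrix
#' @param tissue per-sample "tumor"/"normal" labels
#' @param genes gene symbols to test (subset of \code{colnames(expr)})
#' @param fc_low,fc_high excluded fold-change window
#' @param fdr_threshold FDR cutoff
#' @return data.frame of surviving genes: gene_symbol, fold_change,
#'   p_value, p_fdr, direction; the full tested table is attached as
#'   \code{attr(, "tested")}
#' @export
expressionFilter <- function(expr, tissue, genes, fc_low = 0.5,
                             fc_high = 2.0, fdr_threshold = 0.05) {
  tissue <- as.character(tissue)
  stopifnot(length(tissue) == nrow(expr),
            all(tissue %in% c("tumor", "normal")))
  genes <- unique(genes)
  missing <- setdiff(genes, colnames(expr))
  if (length(missing)) {
    warning("genes absent from the expression matrix: ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  if (!length(genes))
    return(structure(data.frame(gene_symbol = character(0),
                                fold_change = numeric(0), p_value = numeric(0),
                                p_fdr = numeric(0), direction = character(0)),
                     tested = NULL))
  isT <- tissue == "tumor"
  if (sum(isT) < 2L || sum(!isT) < 2L)
    stop("need at least 2 tumor and 2 normal samples")
  sub <- expr[, genes, drop = FALSE]
  meanT <- colMeans(sub[isT, , drop = FALSE])
  meanN <- colMeans(sub[!isT, , drop = FALSE])
  zero <- meanN == 0
  if (any(zero)) {
    warning("zero normal-group mean, fold change undefined: ",
            paste(genes[zero], collapse = ", "))
    sub <- sub[, !zero, drop = FALSE]
    meanT <- meanT[!zero]; meanN <- meanN[!zero]
    genes <- genes[!zero]
  }
  L <- log2(sub + 1)
  w <- .welchRows(L[isT, , drop = FALSE], L[!isT, , drop = FALSE])
  fc <- meanT / meanN
  tested <- data.frame(gene_symbol = genes, fold_change = unname(fc),
                       p_value = unname(w$p_value),
                       p_fdr = stats::p.adjust(w$p_value, "BH"),
                       direction = ifelse(fc > 1, "High", "Low"))
  keep <- (tested$fold_change > fc_high | tested$fold_change < fc_low) &
    tested$p_fdr < fdr_threshold
  out <- tested[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

#' Pairwise LD r-squared from genotype dosages
#'
#' Composite LD: the squared Pearson correlation of the 0/1/2 dosage
#' vectors. Invariant to allele relabeling (\code{a} vs \code{2 - a}).
#'
#' @param a,b equal-length dosage vectors (length >= 3), nonzero variance
#' @param ids optional length-2 SNP names used in error messages
#' @return r-squared in [0, 1]
#' @export
ldR2 <- function(a, b, ids = c("a", "b")) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::var(a) == 0) stop("zero genotype variance for SNP ", ids[1L])
  if (stats::var(b) == 0) stop("zero genotype variance for SNP ", ids[2L])
  stats::cor(a, b)^2
}

#' MAF gate and greedy LD pruning of candidate SNPs
#'
#' First drops SNPs whose reference-panel minor allele frequency is
#' \code{<= maf_threshold}; then prunes for LD greedily: remaining SNPs are
#' sorted by tissue meQTL p-value ascending (ties broken by SNP ID), and a
#' SNP is kept iff its dosage r-squared against every already-kept SNP is
#' below \code{r2_threshold}. Within a correlated cluster this retains the
#' smallest-p representative. The procedure is deterministic and invariant
#' to sample order in the reference panel.
#'
#' @param candidates data.frame with snp_id and meqtl_p_tissue columns
#'   (rows are SNP-CpG pairs; all rows of a surviving SNP are kept)
#' @param ref_genotypes reference samples x SNPs dosage matrix
#' @param maf_threshold MAF gate (strict: keep MAF > threshold)
#' @param r2_threshold LD redundancy cutoff (keep r-squared < threshold)
#' @return surviving \code{candidates} rows with maf_reference and
#'   survived_ld = TRUE appended; attributes "missing_snps",
#'   "dropped_maf" and "dropped_ld" list the exclusions
#' @export
ldPrune <- function(candidates, ref_genotypes, maf_threshold = 0.05,
                    r2_threshold = 0.8) {
  stopifnot("snp_id" %in% names(candidates),
            "meqtl_p_tissue" %in% names(candidates))
  snps <- unique(candidates$snp_id)
  missing <- setdiff(snps, colnames(ref_genotypes))
  snps <- setdiff(snps, missing)
  f <- colMeans(ref_genotypes[, snps, drop = FALSE]) / 2
  maf <- pmin(f, 1 - f)
  droppedMaf <- snps[maf <= maf_threshold]
  snps <- snps[maf > maf_threshold]
  # greedy pruning in order of tissue meQTL p, ties by SNP id
  pOf <- vapply(snps, function(s)
    min(candidates$meqtl_p_tissue[candidates$snp_id == s]), numeric(1))
  ord <- snps[order(pOf, snps)]
  kept <- character(0)
  droppedLd <- character(0)
  for (s in ord) {
    redundant <- any(vapply(kept, function(k)
      ldR2(ref_genotypes[, s], ref_genotypes[, k],
           ids = c(s, k)) >= r2_threshold, logical(1)))
    if (redundant) droppedLd <- c(droppedLd, s) else kept <- c(kept, s)
  }
  out <- candidates[candidates$snp_id %in% kept, , drop = FALSE]
  out$maf_reference <- unname(maf[match(out$snp_id, names(maf))])
  out$survived_ld <- TRUE
  rownames(out) <- NULL
  attr(out, "missing_snps") <- missing
  attr(out, "dropped_maf") <- droppedMaf
  attr(out, "dropped_ld") <- droppedLd
  out
}

#' Run the candidate-axis discovery funnel
#'
#' Composes the post-consensus funnel stages in order: (1) intersection of
#' consensus CpGs with tissue+blood meQTL records ([intersectMeqtl()]),
#' (2) methylation-expression correlation filter ([correlationFilter()]),
#' (3) tumor-vs-normal differential expression filter ([expressionFilter()]),
#' (4) reference-MAF gate and greedy LD pruning ([ldPrune()]). Returns the
#' surviving axis candidates together with a stage-by-stage funnel report
#' whose counts are non-increasing.
#'
#' @param consensus consensus CpG table from [consensusSites()]
#' @param meqtl meQTL record table (see [intersectMeqtl()])
#' @param meth,expr tissue-panel beta and expression matrices (same samples)
#' @param tissue per-sample "tumor"/"normal" labels for the panel
#' @param cpg_gene CpG-to-gene map (columns cpg_id, gene_symbol)
#' @param ref_genotypes reference dosage panel for MAF/LD
#' @param thresholds list from [funnelThresholds()]
#' @return list with \code{candidates} (one row per surviving SNP-CpG-gene
#'   triple with all funnel statistics) and \code{report} (data.frame:
#'   stage, items_in, items_out, threshold)
#' @examples
#' cfg <- simulationConfig(n_tumor_tissue = 100, n_normal_tissue = 50,
#'   n_snps = 6, n_cpgs = 30, n_genes = 10,
#'   planted_axes = plantedAxis(1, 1, 1, meqtl_beta = 1,
#'     tumor_meth_shift = 2, meth_expr_slope = -3, per_allele_log_or = 0),
#'   baseline_expr = 6, seed = 11)
#' co <- tissuePanel(simulateCohort(cfg))
#' dm <- testDifferentialMethylation(methylation(co), phenotype(co)$tissue)
#' cons <- consensusSites(dm, dm)  # toy: same panel twice
#' res <- runFunnel(cons, plantedMeqtlTable(cfg, n_null = 20),
#'                  methylation(co), exprValues(co), phenotype(co)$tissue,
#'                  cpgAnnotation(co), genotypes(co))
#' @export
runFunnel <- function(consensus, meqtl, meth, expr, tissue, cpg_gene,
                      ref_genotypes, thresholds = funnelThresholds()) {
  th <- utils::modifyList(funnelThresholds(), thresholds)
  report <- data.frame(stage = character(0), items_in = integer(0),
                       items_out = integer(0), threshold = character(0))
  addStage <- function(stage, n_in, n_out, threshold) {
    rbind(report, data.frame(stage = stage, items_in = n_in,
                             items_out = n_out, threshold = threshold))
  }
  emptyCand <- data.frame(snp_id = character(0), cpg_id = character(0),
                          gene_symbol = character(0))

  nPairsIn <- nrow(unique(meqtl[, c("snp_id", "cpg_id")]))
  pairs <- tryCatch(
    intersectMeqtl(consensus, meqtl, th$meqtl_fdr, th$require_sign_agreement),
    error = function(e) stop("funnel stage meqtl_intersection: ",
                             conditionMessage(e)))
  report <- addStage("meqtl_intersection", nPairsIn, nrow(pairs),
                     sprintf("FDR < %g in tissue and blood%s", th$meqtl_fdr,
                             if (th$require_sign_agreement) ", signs agree" else ""))
  if (nrow(pairs) == 0L) {
    report <- addStage("methylation_expression_correlation", 0L, 0L,
                       sprintf("|r| > %g, p < %g", th$r, th$r_p))
    report <- addStage("differential_expression", 0L, 0L,
                       sprintf("FC > %g or < %g, FDR < %g",
                               th$fc_high, th$fc_low, th$expr_fdr))
    report <- addStage("maf_ld_prune", 0L, 0L,
                       sprintf("MAF > %g, r2 < %g", th$maf, th$ld_r2))
    return(list(candidates = emptyCand, report = report))
  }

  useT <- if (th$correlation_samples == "tumor")
    as.character(tissue) == "tumor" else rep(TRUE, length(tissue))
  corKept <- tryCatch(
    correlationFilter(meth[useT, , drop = FALSE], expr[useT, , drop = FALSE],
                      pairs, cpg_gene, th$r, th$r_p),
    error = function(e) stop("funnel stage methylation_expression_correlation: ",
                             conditionMessage(e)))
  report <- addStage("methylation_expression_correlation", nrow(pairs),
                     nrow(corKept), sprintf("|r| > %g, p < %g", th$r, th$r_p))

  exprKept <- tryCatch(
    expressionFilter(expr, tissue, corKept$gene_symbol, th$fc_low,
                     th$fc_high, th$expr_fdr),
    error = function(e) stop("funnel stage differential_expression: ",
                             conditionMessage(e)))
  cand <- corKept[corKept$gene_symbol %in% exprKept$gene_symbol, , drop = FALSE]
  idx <- match(cand$gene_symbol, exprKept$gene_symbol)
  cand$expr_fold_change <- exprKept$fold_change[idx]
  cand$expr_p_fdr <- exprKept$p_fdr[idx]
  cand$expr_direction <- exprKept$direction[idx]
  report <- addStage("differential_expression", nrow(corKept), nrow(cand),
                     sprintf("FC > %g or < %g, FDR < %g",
                             th$fc_high, th$fc_low, th$expr_fdr))

  pruned <- tryCatch(
    ldPrune(cand, ref_genotypes, th$maf, th$ld_r2),
    error = function(e) stop("funnel stage maf_ld_prune: ",
                             conditionMessage(e)))
  report <- addStage("maf_ld_prune", nrow(cand), nrow(pruned),
                     sprintf("MAF > %g, r2 < %g", th$maf, th$ld_r2))
  rownames(pruned) <- NULL
  list(candidates = pruned, report = report)
}
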