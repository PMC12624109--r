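## Stage 1 of the funnel: per-CpG tumor-vs-normal differential methylation
## and the cross-dataset consensus call.

.welchRows <- function(x1, x2) {
  # vectorised Welch two-sample t over columns of two matrices
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2L, stats::var); v2 <- apply(x2, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  tstat[degen] <- NA_real_
  p[degen] <- 1
  list(statistic = tstat, p_value = p, degenerate = degen)
}

#' Per-CpG tumor-vs-normal differential methylation
#'
#' Tests every CpG for a tumor-vs-normal methylation difference using
#' Welch's two-sample t-test on M-values (the logit2 transform of the beta
#' values, which stabilizes variance near the 0/1 boundaries), and adjusts
#' the p-values across all tested CpGs by Benjamini-Hochberg. The direction
#' call (Hyper/Hypo) is made on the beta-scale group means; the logistic map
#' is monotone, so the sign agrees with the M-scale difference.
#'
#' CpGs with zero variance in both groups get \code{p_value = 1} and are
#' flagged in the \code{degenerate} column rather than raising an error.
#'
#' @param meth samples x CpGs beta-value matrix, entries strictly in (0, 1)
#' @param tissue character/factor per sample, values "tumor" or "normal";
#'   at least 2 samples per group
#' @return data.frame with one row per CpG, in input column order: cpg_id,
#'   mean_beta_tumor, mean_beta_normal, delta_beta (tumor - normal),
#'   statistic, p_value, p_fdr, direction ("Hyper" iff delta_beta > 0),
#'   degenerate
#' @seealso [consensusSites()]
#' @export
testDifferentialMethylation <- function(meth, tissue) {
  stopifnot(is.matrix(meth), all(meth > 0), all(meth < 1),
            length(tissue) == nrow(meth))
  tissue <- as.character(tissue)
  stopifnot(all(tissue %in% c("tumor", "normal")))
  isT <- tissue == "tumor"
  if (sum(isT) < 2L || sum(!isT) < 2L)
    stop("need at least 2 tumor and 2 normal samples")
  M <- betaToM(meth)
  w <- .welchRows(M[isT, , drop = FALSE], M[!isT, , drop = FALSE])
  mt <- colMeans(meth[isT, , drop = FALSE])
  mn <- colMeans(meth[!isT, , drop = FALSE])
  data.frame(
    cpg_id = colnames(meth),
    mean_beta_tumor = unname(mt),
    mean_beta_normal = unname(mn),
    delta_beta = unname(mt - mn),
    statistic = unname(w$statistic),
    p_value = unname(w$p_value),
    p_fdr = stats::p.adjust(w$p_value, method = "BH"),
    direction = ifelse(mt - mn > 0, "Hyper", "Hypo"),
    degenerate = unname(w$degenerate))
}

#' Consensus differentially methylated CpGs across two datasets
#'
#' Keeps the CpGs that are significant (\code{p_fdr < fdr_threshold}) in
#' BOTH datasets with the SAME direction call. Benjamini-Hochberg adjustment
#' is applied within each dataset separately (by
#' [testDifferentialMethylation()]) before intersecting, so each dataset's
#' FDR is controlled on its own. The operation is symmetric in its two
#' arguments.
#'
#' @param results_a,results_b data.frames from [testDifferentialMethylation()]
#' @param fdr_threshold per-dataset FDR cutoff (strict inequality)
#' @return data.frame with columns cpg_id and direction for the retained
#'   sites; the Hyper/Hypo retention counts are attached as
#'   \code{attr(, "counts")}. An empty intersection warns but is returned.
#' @export
consensusSites <- function(results_a, results_b, fdr_threshold = 0.05) {
  need <- c("cpg_id", "p_fdr", "direction")
  stopifnot(all(need %in% names(results_a)), all(need %in% names(results_b)))
  m <- merge(results_a[, need], results_b[, need], by = "cpg_id",
             suffixes = c("_a", "_b"))
  keep <- m$p_fdr_a < fdr_threshold & m$p_fdr_b < fdr_threshold &
    m$direction_a == m$direction_b
  out <- data.frame(cpg_id = m$cpg_id[keep], direction = m$direction_a[keep])
  out <- out[order(out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(Hyper = sum(out$direction == "Hyper"),
              Hypo = sum(out$direction == "Hypo"))
  if (nrow(out) == 0L)
    warning("no consensus differentially methylated CpGs at FDR < ",
            fdr_threshold)
  attr(out, "counts") <- counts
  out
}
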