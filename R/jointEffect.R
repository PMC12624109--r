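## Joint (allele-dosage-style) effect of co-hypermethylated CpG sites on
## target gene expression: burden counting and trend testing.

#' Co-hypermethylated CpG set around an anchor site
#'
#' Selects, from a region/island of CpGs, the sites that are (a) called
#' Hyper with \code{p_fdr < fdr_threshold} in the differential methylation
#' results and (b) positively correlated with the anchor CpG above
#' \code{r_threshold}. The anchor is always included; if the anchor itself
#' is not a significant Hyper site a warning is raised and the returned set
#' is flagged via \code{attr(, "anchor_hyper") = FALSE}.
#'
#' @param diff_results data.frame from [testDifferentialMethylation()]
#' @param cor_matrix CpG x CpG correlation matrix of beta values (e.g.
#'   \code{cor(methylation)} over the island's columns)
#' @param anchor anchor CpG id (must be a row/column of \code{cor_matrix})
#' @param r_threshold minimum correlation with the anchor (strict)
#' @param fdr_threshold Hyper-call FDR cutoff
#' @return character vector of CpG ids (anchor first)
#' @export
coMethylationSet <- function(diff_results, cor_matrix, anchor,
                             r_threshold = 0.3, fdr_threshold = 0.05) {
  stopifnot(anchor %in% rownames(cor_matrix),
            identical(rownames(cor_matrix), colnames(cor_matrix)),
            all(c("cpg_id", "p_fdr", "direction") %in% names(diff_results)))
  hyper <- diff_results$cpg_id[diff_results$direction == "Hyper" &
                                 diff_results$p_fdr < fdr_threshold]
  anchorHyper <- anchor %in% hyper
  if (!anchorHyper)
    warning("anchor CpG ", anchor,
            " is not a significant hypermethylated site; set returned anyway")
  r <- cor_matrix[anchor, ]
  partners <- names(r)[names(r) != anchor & r > r_threshold]
  partners <- intersect(partners, hyper)
  out <- c(anchor, sort(partners))
  attr(out, "anchor_hyper") <- anchorHyper
  out
}

#' Per-sample hypermethylation burden over a CpG set
#'
#' A sample "carries" a hypermethylated CpG iff its beta value exceeds the
#' normal-reference mean plus \code{k} reference standard deviations at that
#' CpG; the burden is the count of carried CpGs. The k = 1 default is a
#' convention (no standard definition of carrying a hypermethylated site
#' exists) and is deliberately configurable. Raising \code{k} can only
#' lower burdens, and the burden is invariant to CpG column order.
#'
#' @param meth samples x CpGs beta matrix of the samples to score
#' @param cpg_set CpG ids (columns of both matrices)
#' @param normal_ref normal-reference samples x CpGs beta matrix
#'   (>= 2 samples)
#' @param k threshold multiplier on the reference standard deviation
#' @return named integer vector of burdens in [0, length(cpg_set)]
#' @export
burdenPerSample <- function(meth, cpg_set, normal_ref, k = 1) {
  missing <- setdiff(cpg_set, colnames(meth))
  if (length(missing))
    stop("CpG column(s) missing from the methylation matrix: ",
         paste(missing, collapse = ", "))
  missingRef <- setdiff(cpg_set, colnames(normal_ref))
  if (length(missingRef))
    stop("CpG column(s) missing from the normal reference: ",
         paste(missingRef, collapse = ", "))
  stopifnot(nrow(normal_ref) >= 2L, k >= 0)
  ref <- normal_ref[, cpg_set, drop = FALSE]
  thr <- colMeans(ref) + k * apply(ref, 2L, stats::sd)
  hyper <- sweep(meth[, cpg_set, drop = FALSE], 2L, thr, ">")
  out <- as.integer(rowSums(hyper))
  names(out) <- rownames(meth)
  out
}

#' Default burden bins for a seven-CpG set
#'
#' The conventional grouping 0 / 1-3 / 4-6 / 7 carried sites.
#'
#' @return list of integer vectors partitioning 0..7
#' @export
defaultBurdenBins <- function() list(`0` = 0L, `1-3` = 1:3, `4-6` = 4:6, `7` = 7L)

#' Expression trend across hypermethylation-burden groups
#'
#' Groups samples by burden bin, compares each higher bin against the
#' zero-burden bin with a two-sided Mann-Whitney U test (exact where
#' \code{stats::wilcox.test} can be), and measures the overall dose trend by
#' the Spearman correlation of burden against expression. Bins must
#' partition 0..max burden; empty bins are reported and skipped. If all
#' samples fall in one bin the trend is undefined and flagged.
#'
#' @param burden integer burden vector from [burdenPerSample()]
#' @param expression expression vector, same samples/order
#' @param bins named list of integer vectors (default [defaultBurdenBins()])
#' @return list with \code{groups} (data.frame: bin, n, median_expression,
#'   p_vs_zero) and \code{trend} (data.frame: spearman_rho, p_value,
#'   defined)
#' @export
burdenExpressionTest <- function(burden, expression,
                                 bins = defaultBurdenBins()) {
  stopifnot(length(burden) == length(expression),
            all(burden == round(burden)), all(burden >= 0))
  covered <- sort(unique(unlist(bins)))
  if (!setequal(covered, seq(0, max(covered))) ||
      anyDuplicated(unlist(bins)))
    stop("bins must partition 0..max burden without overlap")
  if (max(burden) > max(covered))
    stop("burden values exceed the binning range")
  binOf <- rep(NA_character_, length(burden))
  for (nm in names(bins)) binOf[burden %in% bins[[nm]]] <- nm
  zeroBin <- names(bins)[vapply(bins, function(b) 0L %in% b, logical(1))]
  stopifnot(length(zeroBin) == 1L)

  groups <- do.call(rbind, lapply(names(bins), function(nm) {
    inBin <- binOf == nm
    n <- sum(inBin)
    med <- if (n) stats::median(expression[inBin]) else NA_real_
    p <- NA_real_
    if (nm != zeroBin && n > 0L && sum(binOf == zeroBin) > 0L)
      p <- stats::wilcox.test(expression[inBin],
                              expression[binOf == zeroBin],
                              alternative = "two.sided")$p.value
    data.frame(bin = nm, n = n, median_expression = med, p_vs_zero = p)
  }))
  empty <- groups$bin[groups$n == 0L]
  if (length(empty))
    warning("empty burden bin(s) skipped: ", paste(empty, collapse = ", "))

  defined <- length(unique(burden)) > 1L
  if (defined) {
    ct <- suppressWarnings(stats::cor.test(burden, expression,
                                           method = "spearman"))
    trend <- data.frame(spearman_rho = unname(ct$estimate),
                        p_value = ct$p.value, defined = TRUE)
  } else {
    warning("all samples share one burden value; trend undefined")
    trend <- data.frame(spearman_rho = NA_real_, p_value = NA_real_,
                        defined = FALSE)
  }
  list(groups = groups, trend = trend)
}
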