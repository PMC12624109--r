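## Sign-consistency "biological plausibility" classifier for one
## SNP -> CpG methylation -> gene expression -> disease-risk axis.

#' Classify one axis under the negative-regulation plausibility model
#'
#' Two rules decide whether an axis's SNP-methylation-expression-risk chain
#' is internally sign-consistent under the classical negative-regulation
#' model (promoter hypermethylation silences the gene):
#' \describe{
#'   \item{Rule 1, negative regulation}{passes iff the tumor
#'     methylation-expression correlation r is negative AND the
#'     tumor-vs-normal methylation and expression calls point in opposite
#'     directions (High methylation with Low expression, or vice versa).}
#'   \item{Rule 2, risk concordance}{the predicted odds-ratio side follows
#'     the allele's push on methylation: the variant allele shifting
#'     methylation TOWARD the tumor-like level (beta_sign "+" with tumor
#'     methylation High, or "-" with Low) predicts risk (OR > 1); shifting
#'     away predicts protection (OR < 1). The rule passes iff the observed
#'     OR falls on the predicted side.}
#' }
#' The overall verdict passes iff both rules pass. Axes with positive r are
#' not evaluated under a mirrored positive-regulation model — they simply
#' fail Rule 1. An OR of exactly 1 gives an indeterminate (flagged, failing)
#' Rule 2.
#'
#' @param row one-row data.frame (or list) with beta_sign_tissue,
#'   beta_sign_blood ("+"/"-"), tumor_meth_level, tumor_expr_level
#'   ("High"/"Low"), r (signed correlation) and or_value; an axis id is
#'   taken from snp_id/cpg_id when present
#' @return one-row data.frame: axis_id, rule_negative_regulation,
#'   predicted_or_direction ("risk"/"protective"), rule_or_concordance,
#'   indeterminate_or, overall, narrative
#' @examples
#' classifyAxis(list(snp_id = "rs939408", beta_sign_tissue = "-",
#'   beta_sign_blood = "-", tumor_meth_level = "High",
#'   tumor_expr_level = "Low", r = -0.32, or_value = 0.89))
#' @export
classifyAxis <- function(row) {
  betaT <- row$beta_sign_tissue; betaB <- row$beta_sign_blood
  meth <- row$tumor_meth_level; expr <- row$tumor_expr_level
  r <- row$r; orv <- row$or_value
  stopifnot(betaT %in% c("+", "-"), betaB %in% c("+", "-"),
            meth %in% c("High", "Low"), expr %in% c("High", "Low"),
            is.finite(r), is.finite(orv), orv > 0)
  if (betaT != betaB)
    stop("meQTL effect signs disagree between tissue and blood; axis not classifiable")
  axisId <- paste(c(row$snp_id, row$cpg_id, row$gene_symbol), collapse = "-")
  if (axisId == "") axisId <- NA_character_

  rule1 <- (r < 0) && (meth != expr)
  towardTumor <- (betaT == "+" && meth == "High") ||
    (betaT == "-" && meth == "Low")
  predicted <- if (towardTumor) "risk" else "protective"
  indeterminate <- orv == 1
  rule2 <- !indeterminate &&
    ((predicted == "risk" && orv > 1) || (predicted == "protective" && orv < 1))
  overall <- rule1 && rule2

  narrative <- sprintf(
    paste0("variant allele shifts methylation %s the tumor-like level ",
           "(predicts %s); r %s 0 with %s methylation / %s expression in ",
           "tumor %s the negative-regulation model; observed OR %.2f %s: %s"),
    if (towardTumor) "toward" else "away from", predicted,
    if (r < 0) "<" else ">=", meth, expr,
    if (rule1) "fits" else "violates", orv,
    if (indeterminate) "is indeterminate"
    else if (rule2) "matches the prediction" else "contradicts the prediction",
    if (overall) "PASS" else "FAIL")

  data.frame(axis_id = axisId,
             rule_negative_regulation = rule1,
             predicted_or_direction = predicted,
             rule_or_concordance = rule2,
             indeterminate_or = indeterminate,
             overall = overall,
             narrative = narrative)
}

#' Classify a table of axes and count verdicts
#'
#' Applies [classifyAxis()] to every row and appends pass/fail counts as
#' \code{attr(, "counts")}. On the bundled seven-axis reference table
#' ([loadReferenceAxes()]) exactly the rs939408 and rs66719815 axes pass and
#' the other five fail.
#'
#' @param rows data.frame with the columns [classifyAxis()] requires
#' @return data.frame of verdicts, one row per axis
#' @examples
#' v <- classifyTable(loadReferenceAxes())
#' attr(v, "counts")
#' @export
classifyTable <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    tryCatch(classifyAxis(rows[i, ]),
             error = function(e) stop("axis row ", i, " (",
                                      rows$snp_id[i], "): ",
                                      conditionMessage(e)))
  }))
  rownames(out) <- NULL
  attr(out, "counts") <- c(pass = sum(out$overall), fail = sum(!out$overall))
  out
}
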