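## Case-control additive-model logistic association and genotype-count
## summaries.

#' Variant allele frequency from genotype counts
#'
#' \code{(n1 + 2 * n2) / (2 * (n0 + n1 + n2))}, counting the variant
#' (second) allele of the dosage coding — the "X > Y" string's Y allele.
#' This is the MAF convention used in the bundled reference association
#' table; the value can exceed 0.5 if the counted allele is not actually the
#' minor one in a stratum.
#'
#' @param counts numeric length-3 vector (n0, n1, n2): homozygous-reference,
#'   heterozygous, homozygous-variant sample counts
#' @return allele frequency in [0, 1]
#' @examples
#' mafFromCounts(c(2521, 868, 64))  # 0.1442...
#' @export
mafFromCounts <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero genotype counts")
  unname((counts[2L] + 2 * counts[3L]) / (2 * sum(counts)))
}

#' Expand a genotype-count table to per-sample dosage and status vectors
#'
#' @param cases,controls length-3 genotype counts (n0, n1, n2)
#' @return data.frame with columns dosage (0/1/2) and status (1 = case)
#' @export
expandCounts <- function(cases, controls) {
  stopifnot(length(cases) == 3L, length(controls) == 3L)
  data.frame(
    dosage = c(rep(0:2, times = cases), rep(0:2, times = controls)),
    status = rep(c(1L, 0L), c(sum(cases), sum(controls))))
}

#' Additive-model logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of case status on the variant
#' allele dosage (0/1/2) plus optional covariates. The per-allele odds ratio
#' is \code{exp(coef)}, the 95\% confidence interval is the symmetric Wald
#' interval \code{exp(coef +/- 1.96 * SE)}, and the p-value is the
#' two-sided Wald test. Perfect or quasi-perfect separation is detected
#' (fitted probabilities at the 0/1 boundary or an exploding standard
#' error) and returned as a flagged result with infinite confidence limits
#' rather than silently reported numbers.
#'
#' @param dosages numeric 0/1/2 vector, variance > 0
#' @param status case indicator (1/0, TRUE/FALSE, or "case"/"control")
#' @param covariates optional data.frame of additional adjustment columns
#'   (e.g. age)
#' @param snp_id label carried into the result
#' @return one-row data.frame: snp_id, the two genotype-count triples,
#'   maf_cases, maf_controls, or_value, ci_low, ci_high, p_value,
#'   covariates_used, separation flag
#' @examples
#' d <- expandCounts(c(2521, 868, 64), c(2623, 1002, 85))
#' fitAdditiveLogistic(d$dosage, d$status, snp_id = "rs939408")
#' @export
fitAdditiveLogistic <- function(dosages, status, covariates = NULL,
                                snp_id = NA_character_) {
  if (is.character(status)) status <- status == "case"
  status <- as.integer(status)
  stopifnot(length(dosages) == length(status),
            all(status %in% 0:1), all(dosages %in% 0:2))
  if (sum(status) == 0L || sum(1L - status) == 0L)
    stop("need at least one case and one control")
  if (stats::var(dosages) == 0) stop("zero dosage variance")
  df <- data.frame(status = status, dosage = dosages)
  covNames <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(status))
    covNames <- names(covariates)
    df <- cbind(df, covariates)
  }
  fit <- stats::glm(status ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  co <- summary(fit)$coefficients["dosage", ]
  est <- co[["Estimate"]]; se <- co[["Std. Error"]]
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    se > 100
  if (separated) {
    orv <- exp(est); ciL <- 0; ciH <- Inf; p <- NA_real_
  } else {
    orv <- exp(est)
    ciL <- exp(est - 1.96 * se)
    ciH <- exp(est + 1.96 * se)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  cc <- table(factor(dosages[status == 1L], levels = 0:2))
  nn <- table(factor(dosages[status == 0L], levels = 0:2))
  data.frame(snp_id = snp_id,
             cases_n0 = as.integer(cc[1L]), cases_n1 = as.integer(cc[2L]),
             cases_n2 = as.integer(cc[3L]),
             controls_n0 = as.integer(nn[1L]), controls_n1 = as.integer(nn[2L]),
             controls_n2 = as.integer(nn[3L]),
             maf_cases = mafFromCounts(as.numeric(cc)),
             maf_controls = mafFromCounts(as.numeric(nn)),
             or_value = orv, ci_low = ciL, ci_high = ciH, p_value = p,
             covariates_used = paste(covNames, collapse = ","),
             separation = separated)
}

#' Associate candidate axes with disease in a case-control cohort
#'
#' Fits [fitAdditiveLogistic()] for every candidate SNP and retains those
#' with \code{p < alpha}. No multiple-testing correction is applied at this
#' stage — significance is the nominal per-SNP threshold, as is conventional
#' for a small pre-filtered candidate set — but the Benjamini-Hochberg FDR
#' over the fitted SNPs is computed and reported alongside for transparency
#' (it does not filter). Candidates whose SNP is missing from the genotype
#' matrix are reported in \code{attr(, "missing_snps")}, not fatal.
#'
#' @param candidates data.frame with a snp_id column (rows may be SNP-CpG
#'   pairs; each SNP is fitted once)
#' @param geno samples x SNPs dosage matrix
#' @param status per-sample case indicator (see [fitAdditiveLogistic()])
#' @param covariates optional covariate data.frame (e.g. standardized age)
#' @param alpha retention threshold on the unadjusted p-value
#' @return candidate rows whose SNP is retained, with the association
#'   columns (or_value, ci_low, ci_high, p_value, p_fdr_report,
#'   risk_direction, MAFs and genotype counts) appended; the full per-SNP
#'   fit table is attached as \code{attr(, "fits")}
#' @export
associateCandidates <- function(candidates, geno, status, covariates = NULL,
                                alpha = 0.05) {
  stopifnot("snp_id" %in% names(candidates))
  snps <- unique(candidates$snp_id)
  missing <- setdiff(snps, colnames(geno))
  snps <- setdiff(snps, missing)
  fits <- do.call(rbind, lapply(snps, function(s)
    fitAdditiveLogistic(geno[, s], status, covariates, snp_id = s)))
  if (is.null(fits)) {
    out <- candidates[0, , drop = FALSE]
    attr(out, "fits") <- NULL
    attr(out, "missing_snps") <- missing
    return(out)
  }
  fits$p_fdr_report <- stats::p.adjust(fits$p_value, "BH")
  fits$risk_direction <- ifelse(fits$or_value > 1, "risk", "protective")
  keep <- fits$snp_id[!is.na(fits$p_value) & fits$p_value < alpha]
  out <- merge(candidates[candidates$snp_id %in% keep, , drop = FALSE],
               fits[fits$snp_id %in% keep,
                    c("snp_id", "maf_cases", "maf_controls", "or_value",
                      "ci_low", "ci_high", "p_value", "p_fdr_report",
                      "risk_direction")],
               by = "snp_id", sort = TRUE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "missing_snps") <- missing
  out
}
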