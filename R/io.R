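## Tabular I/O: TSV dialect is UTF-8, tab-delimited, "NA" for missing,
## sample IDs in the first column, feature IDs in the header.

.formatNum <- function(x) {
  # 17 significant digits so doubles round-trip bit-exactly
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  gsub(" ", "", out)
}

#' Read a sample-by-feature matrix from TSV
#'
#' Reads one of the three pipeline matrix kinds with strict validation:
#' every cell must be numeric; genotype entries must be dosages in
#' \{0, 1, 2\}; methylation entries must lie strictly in (0, 1); expression
#' entries must be nonnegative. Sample and feature IDs must be unique and
#' rows must not be ragged. Errors name the offending row and column.
#'
#' @param path TSV file: header of feature IDs, first column sample IDs
#' @param kind one of "genotype", "methylation", "expression"
#' @return numeric matrix (integer for genotypes) with sample row names and
#'   feature column names
#' @seealso [writeCohortMatrix()] for the exact-round-trip writer
#' @export
readCohortMatrix <- function(path, kind = c("genotype", "methylation", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          fill = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("matrix file needs a sample-ID column plus >=1 feature")
  samples <- df[[1L]]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  feats <- colnames(df)[-1L]
  if (anyDuplicated(feats))
    stop("duplicate feature IDs: ", paste(unique(feats[duplicated(feats)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), length(feats),
                dimnames = list(samples, feats))
  for (j in seq_along(feats)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(raw %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   raw[bad[1L]], samples[bad[1L]], feats[j]))
    mat[, j] <- val
  }
  ok <- !is.na(mat)
  if (kind == "genotype") {
    bad <- which(ok & (mat != round(mat) | mat < 0 | mat > 2), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("genotype dosage out of {0,1,2}: value %s at row '%s', column '%s'",
                   mat[bad[1L, 1L], bad[1L, 2L]],
                   samples[bad[1L, 1L]], feats[bad[1L, 2L]]))
    storage.mode(mat) <- "integer"
  } else if (kind == "methylation") {
    bad <- which(ok & (mat <= 0 | mat >= 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("methylation beta outside (0,1): value %s at row '%s', column '%s'",
                   mat[bad[1L, 1L], bad[1L, 2L]],
                   samples[bad[1L, 1L]], feats[bad[1L, 2L]]))
  } else {
    bad <- which(ok & mat < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("negative expression value at row '%s', column '%s'",
                   samples[bad[1L, 1L]], feats[bad[1L, 2L]]))
  }
  mat
}

#' Write a sample-by-feature matrix as TSV
#'
#' Inverse of [readCohortMatrix()]: numbers are formatted with 17 significant
#' digits so a write/read cycle reproduces the matrix exactly and repeated
#' writes of the same object are byte-identical.
#'
#' @param mat numeric matrix with sample row names and feature column names
#' @param path output file
#' @param id_column name for the sample-ID column
#' @return \code{path}, invisibly
#' @export
writeCohortMatrix <- function(mat, path, id_column = "sample_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- apply(mat, 2L, .formatNum)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(mat))
  lines <- c(paste(c(id_column, colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write or read a full cohort directory
#'
#' \code{writeCohort} writes genotypes.tsv, methylation.tsv, expression.tsv,
#' phenotype.tsv, snp_annotation.tsv and cpg_annotation.tsv under \code{dir};
#' \code{readCohort} reassembles the [MeqtlCohort-class]. Identical cohorts
#' produce byte-identical directories.
#'
#' @param cohort a [MeqtlCohort-class]
#' @param dir output/input directory
#' @return \code{writeCohort}: \code{dir} invisibly; \code{readCohort}: a
#'   \code{MeqtlCohort}
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "MeqtlCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCohortMatrix(genotypes(cohort), file.path(dir, "genotypes.tsv"))
  writeCohortMatrix(methylation(cohort), file.path(dir, "methylation.tsv"))
  writeCohortMatrix(exprValues(cohort), file.path(dir, "expression.tsv"))
  ph <- as.data.frame(phenotype(cohort))
  ph <- data.frame(sample_id = rownames(ph), ph[, c("role", "tissue", "status")],
                   age = .formatNum(ph$age))
  utils::write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  snpAnn <- snpAnnotation(cohort)
  if ("maf" %in% names(snpAnn)) snpAnn$maf <- .formatNum(snpAnn$maf)
  utils::write.table(snpAnn, file.path(dir, "snp_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cpgAnnotation(cohort), file.path(dir, "cpg_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  geno <- readCohortMatrix(file.path(dir, "genotypes.tsv"), "genotype")
  meth <- readCohortMatrix(file.path(dir, "methylation.tsv"), "methylation")
  expr <- readCohortMatrix(file.path(dir, "expression.tsv"), "expression")
  ph <- utils::read.table(file.path(dir, "phenotype.tsv"), header = TRUE,
                          sep = "\t", quote = "", na.strings = "NA",
                          colClasses = c("character", "character", "character",
                                         "character", "numeric"))
  pheno <- S4Vectors::DataFrame(role = ph$role, tissue = ph$tissue,
                                status = ph$status, age = ph$age,
                                row.names = ph$sample_id)
  snpAnn <- utils::read.table(file.path(dir, "snp_annotation.tsv"),
                              header = TRUE, sep = "\t", quote = "",
                              na.strings = "NA", stringsAsFactors = FALSE)
  cpgAnn <- utils::read.table(file.path(dir, "cpg_annotation.tsv"),
                              header = TRUE, sep = "\t", quote = "",
                              na.strings = "NA", stringsAsFactors = FALSE)
  new("MeqtlCohort", genotypes = geno, methylation = meth, expression = expr,
      phenotype = pheno, snpAnnotation = snpAnn, cpgAnnotation = cpgAnn)
}

#' Read a marker annotation table
#'
#' Accepts either the native 1-based annotation table (columns feature_id,
#' chromosome, position, and optionally gene_symbol / alleles) or a 4-column
#' BED-like TSV (chrom, start, end, id; 0-based half-open), which is
#' converted explicitly to 1-based fully-closed positions. SNP allele strings
#' must match \code{[ACGT]+>[ACGT]+}; the second allele is the variant
#' (counted) allele throughout the package.
#'
#' @param path TSV file
#' @param format "native" or "bed"
#' @return data.frame with columns feature_id, chromosome, position (1-based)
#'   plus any extra native columns
#' @export
readAnnotation <- function(path, format = c("native", "bed")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = (format == "native"), sep = "\t",
                          quote = "", na.strings = "NA",
                          stringsAsFactors = FALSE, fill = FALSE)
  if (format == "bed") {
    if (ncol(df) < 4L) stop("BED-like annotation needs 4 columns: chrom, start, end, id")
    df <- data.frame(feature_id = df[[4L]], chromosome = df[[1L]],
                     position = df[[2L]] + 1L)  # 0-based start -> 1-based
  } else {
    need <- c("feature_id", "chromosome", "position")
    if (!all(need %in% names(df)))
      stop("native annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$position <= 0)) stop("annotation positions must be positive (1-based)")
  if ("alleles" %in% names(df)) {
    ok <- is.na(df$alleles) | grepl("^[ACGT]+>[ACGT]+$", df$alleles)
    if (!all(ok))
      stop("malformed allele string(s): ",
           paste(df$alleles[!ok], collapse = ", "))
  }
  df
}

#' Load the bundled seven-axis reference tables
#'
#' Returns the package's reference table of seven candidate meQTL axes from a
#' genome-wide case-control susceptibility study of non-smoking lung
#' adenocarcinoma (3453 cases, 3710 controls): per-axis meQTL effect signs
#' and p-values in lung tissue and blood, tumor-vs-normal methylation and
#' expression levels, the tumor methylation-expression correlation r, the
#' case/control genotype counts and the age-adjusted additive-model odds
#' ratio with its 95\% confidence interval.
#'
#' One CpG (cg09596674) is annotated with two discordant published positions;
#' both are retained (\code{position}, \code{position_alt}) with
#' \code{position_flag = "discordant_sources"} rather than silently resolved.
#'
#' @return data.frame with 7 rows, one per SNP-CpG-gene axis
#' @examples
#' axes <- loadReferenceAxes()
#' axes[axes$snp_id == "rs939408", c("beta_sign_tissue", "r", "or_value")]
#' @export
loadReferenceAxes <- function() {
  f1 <- system.file("extdata", "candidate_axes_summary.tsv",
                    package = "meqaxis", mustWork = TRUE)
  f2 <- system.file("extdata", "candidate_axes_association.tsv",
                    package = "meqaxis", mustWork = TRUE)
  a <- utils::read.table(f1, header = TRUE, sep = "\t", quote = "",
                         na.strings = "NA", stringsAsFactors = FALSE)
  b <- utils::read.table(f2, header = TRUE, sep = "\t", quote = "",
                         na.strings = "NA", stringsAsFactors = FALSE)
  out <- merge(a, b[, setdiff(names(b), c("gene_symbol", "chromosome", "position"))],
               by = c("no", "cpg_id", "snp_id"), sort = FALSE)
  out <- out[order(out$no), ]
  rownames(out) <- NULL
  stopifnot(nrow(out) == 7L,
            all(out$beta_sign_tissue %in% c("+", "-")),
            all(out$beta_sign_blood %in% c("+", "-")),
            all(out$tumor_meth_level %in% c("High", "Low")),
            all(out$tumor_expr_level %in% c("High", "Low")),
            all(out$meqtl_p_tissue > 0 & out$meqtl_p_tissue <= 1),
            all(out$meqtl_p_blood > 0 & out$meqtl_p_blood <= 1),
            all(abs(out$r) <= 1),
            all(out$ci_low <= out$or_value & out$or_value <= out$ci_high),
            all(grepl("^[ACGT]+>[ACGT]+$", out$alleles)))
  out
}
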