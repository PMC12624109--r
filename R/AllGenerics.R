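#' Accessors for MeqtlCohort components
#'
#' @param x a [MeqtlCohort-class]
#' @return \code{genotypes}: integer dosage matrix (samples x SNPs);
#'   \code{methylation}: beta-value matrix (samples x CpGs);
#'   \code{exprValues}: expression matrix (samples x genes);
#'   \code{phenotype}: per-sample DataFrame;
#'   \code{snpAnnotation}/\code{cpgAnnotation}: marker annotation data.frames.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname cohort-accessors
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))

#' @rdname cohort-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname cohort-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname cohort-accessors
#' @export
setGeneric("snpAnnotation", function(x) standardGeneric("snpAnnotation"))

#' @rdname cohort-accessors
#' @export
setGeneric("cpgAnnotation", function(x) standardGeneric("cpgAnnotation"))

#' @rdname cohort-accessors
setMethod("genotypes", "MeqtlCohort", function(x) x@genotypes)

#' @rdname cohort-accessors
setMethod("methylation", "MeqtlCohort", function(x) x@methylation)

#' @rdname cohort-accessors
setMethod("exprValues", "MeqtlCohort", function(x) x@expression)

#' @rdname cohort-accessors
setMethod("phenotype", "MeqtlCohort", function(x) x@phenotype)

#' @rdname cohort-accessors
setMethod("snpAnnotation", "MeqtlCohort", function(x) x@snpAnnotation)

#' @rdname cohort-accessors
setMethod("cpgAnnotation", "MeqtlCohort", function(x) x@cpgAnnotation)

#' Subset a cohort to the tumor/normal tissue panel or the case-control cohort
#'
#' @param x a [MeqtlCohort-class]
#' @return a \code{MeqtlCohort} restricted to the requested samples
#' @name cohort-subsets
NULL

#' @rdname cohort-subsets
#' @export
setGeneric("tissuePanel", function(x) standardGeneric("tissuePanel"))

#' @rdname cohort-subsets
#' @export
setGeneric("associationCohort", function(x) standardGeneric("associationCohort"))

.subsetCohort <- function(x, keep) {
  new("MeqtlCohort",
      genotypes = x@genotypes[keep, , drop = FALSE],
      methylation = x@methylation[keep, , drop = FALSE],
      expression = x@expression[keep, , drop = FALSE],
      phenotype = x@phenotype[keep, , drop = FALSE],
      snpAnnotation = x@snpAnnotation,
      cpgAnnotation = x@cpgAnnotation)
}

#' @rdname cohort-subsets
setMethod("tissuePanel", "MeqtlCohort", function(x)
  .subsetCohort(x, x@phenotype$role == "tissue"))

#' @rdname cohort-subsets
setMethod("associationCohort", "MeqtlCohort", function(x)
  .subsetCohort(x, x@phenotype$role == "cohort"))
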