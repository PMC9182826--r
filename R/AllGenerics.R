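#' Accessors for grsMR objects
#'
#' @param x a grsMR object.
#' @param ... passed to methods.
#' @name grsMR-accessors
NULL

#' @describeIn grsMR-accessors SNPs x samples dosage matrix (`NA` = missing).
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @describeIn grsMR-accessors logical SNPs x samples missingness mask.
#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))

#' @describeIn grsMR-accessors per-SNP weight records as a `data.frame`.
#' @export
setGeneric("snpWeights", function(x, ...) standardGeneric("snpWeights"))

#' @describeIn grsMR-accessors per-sample cohort table as a `data.frame`.
#' @export
setGeneric("cohortData", function(x, ...) standardGeneric("cohortData"))

#' @describeIn grsMR-accessors named per-sample scores of a [GrsVector-class].
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @describeIn grsMR-accessors provenance log of a [GrsVector-class].
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @describeIn grsMR-accessors ratio-scale point estimate of an
#'   [MrEstimate-class] (HR or OR).
#' @export
setGeneric("estimate", function(x, ...) standardGeneric("estimate"))

#' @describeIn grsMR-accessors 95% confidence interval of an
#'   [MrEstimate-class], ratio scale.
#' @export
setGeneric("confint95", function(x, ...) standardGeneric("confint95"))
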