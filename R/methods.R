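#' @rdname grsMR-accessors
#' @aliases dosages,GenotypePanel-method
setMethod("dosages", "GenotypePanel", function(x, ...) {
  SummarizedExperiment::assay(x, "dosage")
})

#' @rdname grsMR-accessors
#' @aliases missingMask,GenotypePanel-method
setMethod("missingMask", "GenotypePanel", function(x, ...) {
  is.na(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname grsMR-accessors
#' @aliases snpWeights,GenotypePanel-method
setMethod("snpWeights", "GenotypePanel", function(x, ...) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  df <- cbind(snp_id = rownames(x), df)
  rownames(df) <- NULL
  df
})

#' @rdname grsMR-accessors
#' @aliases cohortData,GenotypePanel-method
setMethod("cohortData", "GenotypePanel", function(x, ...) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  if (!"sample_id" %in% names(df)) df <- cbind(sample_id = colnames(x), df)
  rownames(df) <- NULL
  df
})

setMethod("show", "GenotypePanel", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  cat("GenotypePanel:", nrow(object), "SNPs x", ncol(object), "samples\n")
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(d))))
  rd <- names(SummarizedExperiment::rowData(object))
  cd <- names(SummarizedExperiment::colData(object))
  if (length(rd)) cat("  snp fields:", paste(rd, collapse = ", "), "\n")
  if (length(cd)) cat("  cohort fields:", paste(utils::head(cd, 12), collapse = ", "),
                      if (length(cd) > 12) "..." else "", "\n")
  invisible(NULL)
})

#' @rdname grsMR-accessors
#' @aliases scores,GrsVector-method
setMethod("scores", "GrsVector", function(x, ...) x@score)

#' @rdname grsMR-accessors
#' @aliases provenance,GrsVector-method
setMethod("provenance", "GrsVector", function(x, ...)
  list(snps = x@snps, log = x@log))

setMethod("show", "GrsVector", function(object) {
  cat("GrsVector:", length(object@score), "samples,",
      nrow(object@snps), "SNPs retained\n")
  if (length(object@score))
    cat(sprintf("  score mean %.3f, sd %.3f\n",
                mean(object@score), sd(object@score)))
  invisible(NULL)
})

setMethod("show", "MrScenario", function(object) {
  cat("MrScenario:", object@nSamples, "samples,", object@nSnps, "SNPs\n")
  cat(sprintf("  instrument R2 %.3f | causal log HR %.4f (HR %.3f) | confounder %.2f/%.2f\n",
              object@instrumentR2, object@causalLogHr, exp(object@causalLogHr),
              object@confounderEffectExposure, object@confounderLogHr))
  cat(sprintf("  pleiotropy %.4f +/- %.4f | baseline hazard %.2e/y | seed %d\n",
              object@pleiotropyMean, object@pleiotropySd,
              object@baselineHazard, object@seed))
  invisible(NULL)
})

#' @rdname grsMR-accessors
#' @aliases estimate,MrEstimate-method
setMethod("estimate", "MrEstimate", function(x, ...) exp(x@logEstimate))

#' @rdname grsMR-accessors
#' @aliases confint95,MrEstimate-method
setMethod("confint95", "MrEstimate", function(x, ...)
  c(x@ciLow, x@ciHigh))

setMethod("show", "MrEstimate", function(object) {
  ratio <- if (object@estimator == "two_stage_logistic") "OR" else "HR"
  cat(sprintf("MrEstimate [%s], %s\n", object@estimator, object@scale))
  cat(sprintf("  %s %.3f (95%% CI %.3f-%.3f), p = %.3g\n", ratio,
              exp(object@logEstimate), object@ciLow, object@ciHigh, object@p))
  if (!is.null(object@extras$interceptP))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n",
                object@extras$intercept, object@extras$interceptP))
  if (!is.null(object@extras$F))
    cat(sprintf("  first-stage F = %.1f\n", object@extras$F))
  invisible(NULL)
})

#' Flatten an MrEstimate to one results row
#'
#' @param x an [MrEstimate-class].
#' @param row.names,optional,... ignored (base signature).
#' @return A one-row `data.frame` with columns `estimator`, `scale`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `se_log`, `n`, `events`,
#'   `f_stat`, `egger_intercept`, `egger_intercept_p`.
#' @export
as.data.frame.MrEstimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    estimator = x@estimator, scale = x@scale,
    estimate = exp(x@logEstimate), ci_low = x@ciLow, ci_high = x@ciHigh,
    p = x@p, se_log = x@se, n = x@n, events = x@events,
    f_stat = if (is.null(x@extras$F)) NA_real_ else x@extras$F,
    egger_intercept = if (is.null(x@extras$intercept)) NA_real_ else x@extras$intercept,
    egger_intercept_p = if (is.null(x@extras$interceptP)) NA_real_ else x@extras$interceptP,
    stringsAsFactors = FALSE)
}

setMethod("show", "QuintileResult", function(object) {
  cat("QuintileResult: 5 groups, reference =", object@reference, "\n")
  g <- object@groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  Q%d  n=%d events=%d  HR %s\n", g$group[i], g$n[i], g$events[i],
                if (i == object@reference) "1 (ref)"
                else sprintf("%.2f (%.2f-%.2f)", g$hr[i], g$ciLow[i], g$ciHigh[i])))
  cat(sprintf("  trend slope %.4f (SE %.4f) per exposure unit\n",
              object@trendSlope, object@trendSe))
  invisible(NULL)
})
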