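#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0,1).
#' @param k number of tests (>= 1).
#' @return `alpha / k`.
#' @examples
#' round(bonferroniThreshold(0.05, 28), 4)  # 0.0018
#' @export
bonferroniThreshold <- function(alpha, k) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  alpha / k
}

#' Declare an exposure for the observational scan
#'
#' @param name cohort column holding the exposure.
#' @param unit reporting-unit scaling: the hazard ratio is reported per
#'   `unit` of the exposure (`HR_unit = exp(coef * unit)`), e.g. 10 for
#'   "per 10 mmHg".
#' @param model covariate adjustment set id (see [covariateModel()]);
#'   lipid exposures use `"observational_lipid"`.
#' @return one-row `data.frame`; `rbind` rows into a registry.
#' @export
exposureSpec <- function(name, unit = 1,
                         model = c("observational", "observational_lipid",
                                   "mr")) {
  stopifnot(unit > 0)
  data.frame(name = name, unit = unit, model = match.arg(model),
             stringsAsFactors = FALSE)
}

#' Observational Cox scan over an exposure registry
#'
#' Fits one Cox proportional-hazards model per exposure under its declared
#' adjustment set, on incident cases only (prevalent cases are removed).
#' Hazard ratios are rescaled to each exposure's reporting unit, the
#' proportional-hazards assumption is checked per exposure, and
#' significance is flagged at `alpha` and at the Bonferroni-corrected
#' `alpha / k`.
#'
#' @param cohort cohort `data.frame` (see [readCohortTable()]).
#' @param exposures registry built from [exposureSpec()] rows.
#' @param alpha raw significance level.
#' @param k number of tests for the Bonferroni correction; defaults to the
#'   registry size.
#' @return `data.frame` with one row per scanned exposure: `exposure`,
#'   `unit`, `hr`, `ci_low`, `ci_high`, `p`, `ph_p`, `ph_ok`, `n`,
#'   `events`, `sig_raw`, `sig_bonferroni`; skipped exposures are recorded
#'   in `attr(, "log")`.
#' @export
runExposureScan <- function(cohort, exposures, alpha = 0.05,
                            k = nrow(exposures)) {
  stopifnot(nrow(exposures) >= 1L)
  cohort <- cohort[cohort$prevalent == 0L, , drop = FALSE]
  bonf <- bonferroniThreshold(alpha, k)
  rows <- list()
  log <- character(0)
  for (i in seq_len(nrow(exposures))) {
    nm <- exposures$name[i]
    unit <- exposures$unit[i]
    if (!nm %in% names(cohort)) {
      log <- c(log, paste0(nm, ": column absent, skipped"))
      next
    }
    covars <- covariateModel(cohort, exposures$model[i])
    ok <- complete.cases(cohort[[nm]], covars)
    x <- cohort[[nm]][ok]
    if (length(unique(x)) < 2L) {
      log <- c(log, paste0(nm, ": constant exposure, skipped"))
      next
    }
    design <- cbind(data.frame(.exposure = x), covars[ok, , drop = FALSE])
    fit <- fitCox(cohort$followup_years[ok], cohort$event[ok], design)
    co <- fit$coef[fit$coef$term == ".exposure", ]
    ph <- phTest(fit)
    phP <- ph$p[ph$term == ".exposure"]
    rows[[nm]] <- data.frame(
      exposure = nm, unit = unit,
      hr = exp(co$estimate * unit),
      ci_low = exp((co$estimate - 1.96 * co$se) * unit),
      ci_high = exp((co$estimate + 1.96 * co$se) * unit),
      p = co$p, ph_p = phP, ph_ok = phP > 0.05,
      n = fit$n, events = fit$events,
      sig_raw = co$p < alpha, sig_bonferroni = co$p < bonf,
      stringsAsFactors = FALSE)
  }
  out <- .rbindRows(rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "log") <- log
  attr(out, "bonferroni_threshold") <- bonf
  out
}

#' Quintile dose-response analysis
#'
#' Splits a continuous variable into equal-frequency fifths (cut points
#' from the analysis sample; values equal to a cut point fall in the lower
#' group), fits a Cox model with four indicator terms against the lowest
#' fifth, and adds an inverse-variance-weighted log-linear trend across
#' group medians.
#'
#' @param exposure continuous values (an observed phenotype or a genetic
#'   prediction) with at least 5 distinct values.
#' @param followup,event survival outcome (incident cases only).
#' @param covariates optional covariate `data.frame` (same rows).
#' @return A [QuintileResult-class].
#' @export
quintileAnalysis <- function(exposure, followup, event, covariates = NULL) {
  q <- .quintileGroups(exposure)
  grp <- factor(q$group, levels = 1:5)
  design <- data.frame(.quintile = grp)
  if (!is.null(covariates)) design <- cbind(design, covariates)
  fit <- fitCox(followup, event, design)
  co <- fit$coef[grepl("^\\.quintile", fit$coef$term), ]
  logHr <- c(0, co$estimate)
  se <- c(NA_real_, co$se)
  groups <- data.frame(
    group = 1:5,
    n = as.integer(table(grp)),
    events = as.integer(tapply(event, grp, sum)),
    median = as.numeric(tapply(exposure, grp, median)),
    logHr = logHr, se = se,
    hr = exp(logHr),
    ciLow = c(NA_real_, exp(co$estimate - 1.96 * co$se)),
    ciHigh = c(NA_real_, exp(co$estimate + 1.96 * co$se)))
  res <- new("QuintileResult", cutPoints = q$cuts, groups = groups,
             reference = 1L, trendSlope = NA_real_, trendSe = NA_real_)
  tr <- trendFit(res)
  res@trendSlope <- tr$slope
  res@trendSe <- tr$se
  validObject(res)
  res
}

#' Inverse-variance-weighted trend across quintile groups
#'
#' Weighted least squares of group log HR on group median exposure with
#' weights `1/se^2`. The reference group enters at log HR 0; its sampling
#' variance is zero by construction (an infinite weight), so it is capped
#' at the largest finite weight among the other groups to keep the fit
#' defined. The slope standard error uses the fixed-weight
#' (known-variance) formula `sqrt(1 / sum(w (x - xbar_w)^2))`.
#'
#' @param quintileResult a [QuintileResult-class].
#' @return list with `slope` and `se` (per exposure unit).
#' @export
trendFit <- function(quintileResult) {
  g <- quintileResult@groups
  ref <- quintileResult@reference
  w <- 1 / g$se^2
  if (sum(is.finite(w[-ref])) < 2L)
    stop("trend fit needs >= 2 non-reference groups with finite SEs")
  w[ref] <- max(w[-ref][is.finite(w[-ref])])
  keep <- is.finite(w) & is.finite(g$logHr)
  x <- g$median[keep]; y <- g$logHr[keep]; w <- w[keep]
  xb <- weighted.mean(x, w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("trend fit undefined: no spread in group medians")
  slope <- sum(w * (x - xb) * y) / sxx
  list(slope = slope, se = sqrt(1 / sxx))
}

#' Reverse-causation sensitivity exclusions
#'
#' @param cohort cohort `data.frame`.
#' @param rule `drop_lipid_med_users` removes baseline users of
#'   cholesterol-lowering medication; `drop_followup_lt_3y` removes
#'   participants with strictly less than three years of follow-up
#'   (exactly 3.0 years is retained); `both` applies both.
#' @return list with the filtered `cohort` and `removed`, the count removed
#'   per rule.
#' @export
sensitivityExclusions <- function(cohort,
                                  rule = c("drop_lipid_med_users",
                                           "drop_followup_lt_3y", "both")) {
  rule <- match.arg(rule)
  removed <- c(lipid_med_users = 0L, followup_lt_3y = 0L)
  if (rule %in% c("drop_lipid_med_users", "both")) {
    drop <- cohort$lipid_med == 1L
    removed["lipid_med_users"] <- sum(drop)
    cohort <- cohort[!drop, , drop = FALSE]
  }
  if (rule %in% c("drop_followup_lt_3y", "both")) {
    drop <- cohort$followup_years < 3
    removed["followup_lt_3y"] <- sum(drop)
    cohort <- cohort[!drop, , drop = FALSE]
  }
  if (nrow(cohort) == 0L) stop("exclusions removed every participant")
  list(cohort = cohort, removed = removed)
}
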