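#' Stage one: regress the exposure on the genetic risk score
#'
#' Linear regression of the phenotype on the weighted GRS and the MR
#' covariates (sex, age, ten principal components, chip). The genetic
#' prediction is the fitted genetic component `gamma_hat * GRS`; for a
#' continuous exposure it is z-standardized on the analysis sample (mean 0,
#' SD 1), defining the "per 1-SD genetically predicted" unit. For a binary
#' exposure stage one is a linear probability model and the prediction is
#' left on the probability scale ("per category"). The instrument-strength
#' F-statistic is the squared t of the GRS term; an F below 10 triggers a
#' weak-instrument warning but the analysis proceeds.
#'
#' @param grs numeric GRS per sample (see [computeGrs()]).
#' @param exposure phenotype per sample (0/1 when `binary`).
#' @param covariates covariate `data.frame` (same rows), typically
#'   `covariateModel(cohort, "mr")`.
#' @param binary treat the exposure as binary ("per category" scale)?
#' @param standardizeBinary also z-standardize a binary exposure's
#'   prediction (sensitivity switch; default keeps the per-category scale).
#' @return list of class `StageOneFit`: `fit` ([fitLinear()] result),
#'   `prediction`, `gammaHat`, `fStat`, `partialR2`, `scale`, `weak`.
#' @export
stageOne <- function(grs, exposure, covariates, binary = FALSE,
                     standardizeBinary = FALSE) {
  design <- cbind(data.frame(.grs = grs), covariates)
  fit <- fitLinear(exposure, design, term = ".grs")
  gammaHat <- fit$coef$estimate[fit$coef$term == ".grs"]
  pred <- gammaHat * grs
  scale <- if (binary && !standardizeBinary) "per category" else "per 1-SD"
  predictionSd <- sd(pred)
  exposureSd <- if (binary) 1 else sd(exposure)
  if (scale == "per 1-SD") {
    if (predictionSd == 0)
      stop("degenerate genetic prediction: zero variance")
    pred <- (pred - mean(pred)) / predictionSd
  }
  if (fit$fStat < 10)
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", fit$fStat))
  structure(list(fit = fit, prediction = pred, gammaHat = gammaHat,
                 fStat = fit$fStat, partialR2 = fit$partialR2,
                 scale = scale, weak = fit$fStat < 10,
                 predictionSd = predictionSd, exposureSd = exposureSd,
                 # second-stage coefficients on the standardized prediction
                 # are per SD of the *prediction*; multiplying by this factor
                 # returns them to the per-1-SD-of-exposure reporting unit
                 rescale = if (scale == "per 1-SD")
                   exposureSd / predictionSd else 1),
            class = "StageOneFit")
}

#' Stage two: Cox model on the genetic prediction (incident cases)
#'
#' Cox proportional-hazards regression of incident events on the
#' standardized genetic prediction plus the MR covariates. The reported
#' standard error is the naive second-stage one (no correction for
#' first-stage estimation), the usual choice for one-sample GRS analyses
#' with strong instruments.
#'
#' @param prediction standardized genetic prediction from [stageOne()].
#' @param followup,event incident follow-up and event indicator (prevalent
#'   cases must already be excluded).
#' @param covariates MR covariate `data.frame`.
#' @param scale reporting scale recorded on the estimate.
#' @param rescale factor returning the coefficient on the standardized
#'   prediction to the exposure's reporting unit (`rescale` element of the
#'   [stageOne()] fit: the fitted value, not its z-score, carries the
#'   exposure scale, so the z-scale coefficient is multiplied by
#'   `exposureSd / predictionSd` to express the effect per 1 SD of the
#'   exposure).
#' @return An [MrEstimate-class] (hazard-ratio scale).
#' @export
stageTwoCox <- function(prediction, followup, event, covariates,
                        scale = "per 1-SD", rescale = 1) {
  design <- cbind(data.frame(.pred = prediction), covariates)
  fit <- fitCox(followup, event, design)
  co <- fit$coef[fit$coef$term == ".pred", ]
  .MrEstimate("two_stage_cox", scale, co$estimate * rescale,
              co$se * rescale, n = fit$n, events = fit$events)
}

#' Stage two robustness: logistic model on all cases
#'
#' Logistic regression of case status (incident or prevalent) on the
#' genetic prediction plus the MR covariates, reported as an odds ratio.
#'
#' @param prediction standardized genetic prediction.
#' @param case 0/1 indicator of incident-or-prevalent case status.
#' @param covariates MR covariate `data.frame`.
#' @param scale reporting scale recorded on the estimate.
#' @param rescale reporting-unit factor, as in [stageTwoCox()].
#' @return An [MrEstimate-class] (odds-ratio scale).
#' @export
stageTwoLogistic <- function(prediction, case, covariates,
                             scale = "per 1-SD", rescale = 1) {
  design <- cbind(data.frame(.pred = prediction), covariates)
  fit <- fitLogistic(case, design)
  co <- fit$coef[fit$coef$term == ".pred", ]
  .MrEstimate("two_stage_logistic", scale, co$estimate * rescale,
              co$se * rescale, n = fit$n, events = sum(case))
}

#' Per-SNP exposure and outcome associations
#'
#' For each SNP of a pruned, imputed panel: the exposure association from a
#' linear regression of the phenotype on the dosage plus the MR covariates,
#' and the outcome association (log hazard ratio) from a Cox model of the
#' incident outcome on the dosage plus the same covariates. These summaries
#' feed the pleiotropy-robust estimators. SNPs whose fits fail are dropped
#' with a log entry; at least `minSnps` must survive.
#'
#' @param panel complete [GenotypePanel-class].
#' @param exposure phenotype per sample.
#' @param followup,event incident outcome (prevalent cases excluded).
#' @param covariates MR covariate `data.frame`.
#' @param minSnps minimum surviving SNPs (3: the Egger line needs them).
#' @return `data.frame` with `snp_id`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`; dropped SNPs in `attr(, "log")`.
#' @export
perSnpAssociations <- function(panel, exposure, followup, event, covariates,
                               minSnps = 3L) {
  d <- dosages(panel)
  if (anyNA(d)) stop("panel has missing dosages; run imputeMissing() first")
  rows <- list()
  log <- character(0)
  for (id in rownames(d)) {
    g <- d[id, ]
    res <- tryCatch({
      lf <- fitLinear(exposure, cbind(data.frame(.g = g), covariates),
                      term = ".g")
      cf <- fitCox(followup, event,
                   cbind(data.frame(.g = g), covariates))
      le <- lf$coef[lf$coef$term == ".g", ]
      ce <- cf$coef[cf$coef$term == ".g", ]
      data.frame(snp_id = id, beta_exp = le$estimate, se_exp = le$se,
                 beta_out = ce$estimate, se_out = ce$se,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) log <- c(log, paste0(id, ": ", res))
    else rows[[id]] <- res
  }
  if (length(rows) < minSnps)
    stop("fewer than ", minSnps, " SNPs with valid per-SNP fits")
  out <- .rbindRows(rows)
  attr(out, "log") <- log
  out
}

# orient every SNP so its exposure association is positive
.orient <- function(s) {
  flip <- sign(s$beta_exp)
  flip[flip == 0] <- 1
  s$beta_exp <- s$beta_exp * flip
  s$beta_out <- s$beta_out * flip
  s
}

#' MR-Egger regression
#'
#' Weighted linear regression (weights `1/se_out^2`) of per-SNP outcome
#' associations on exposure associations with a free intercept, after
#' orienting all SNPs to positive exposure effects. The slope estimates the
#' causal log hazard ratio per exposure unit (rescaled to per-SD via
#' `exposureSd`); a nonzero intercept indicates directional horizontal
#' pleiotropy, and its two-sided p-value (t test from the weighted
#' regression) is the pleiotropy diagnostic.
#'
#' @param snpSummary result of [perSnpAssociations()].
#' @param exposureSd SD of the exposure, to rescale the slope to a per-SD
#'   effect (1 if the exposure is already standardized).
#' @param scale reporting scale recorded on the estimate.
#' @return An [MrEstimate-class] with `intercept`, `interceptSe`,
#'   `interceptP` and `nSnps` in `extras`.
#' @export
mrEgger <- function(snpSummary, exposureSd = 1, scale = "per 1-SD") {
  s <- .orient(snpSummary)
  if (nrow(s) < 3L) stop("MR-Egger needs at least 3 SNPs")
  if (diff(range(s$beta_exp)) < 1e-12)
    stop("degenerate exposure-association spread: Egger slope unidentified")
  w <- 1 / s$se_out^2
  fit <- lm(beta_out ~ beta_exp, data = s, weights = w)
  sm <- summary(fit)$coefficients
  slope <- sm["beta_exp", 1L] * exposureSd
  slopeSe <- sm["beta_exp", 2L] * exposureSd
  est <- .MrEstimate("mr_egger", scale, slope, slopeSe,
                     extras = list(intercept = sm["(Intercept)", 1L],
                                   interceptSe = sm["(Intercept)", 2L],
                                   interceptP = sm["(Intercept)", 4L],
                                   nSnps = nrow(s)))
  # slope p from the regression t rather than the normal approximation
  est@p <- sm["beta_exp", 4L]
  est
}

#' Weighted-median estimator
#'
#' Per-SNP Wald ratios `beta_out / beta_exp` with first-order delta-method
#' inverse-variance weights `beta_exp^2 / se_out^2`; the estimate is the
#' weighted median (linear interpolation of the normalized cumulative
#' weights to the 50% point), consistent when at least half of the weight
#' comes from valid instruments. The standard error comes from a
#' parametric bootstrap that resamples per-SNP associations from their
#' normal sampling distributions.
#'
#' @param snpSummary result of [perSnpAssociations()]; SNPs with a zero
#'   exposure association are dropped (at least 3 must remain).
#' @param nBoot bootstrap replicates.
#' @param seed optional seed for the bootstrap stream.
#' @param exposureSd SD of the exposure for per-SD rescaling.
#' @param scale reporting scale recorded on the estimate.
#' @return An [MrEstimate-class] with `nSnps` in `extras`.
#' @export
weightedMedian <- function(snpSummary, nBoot = 1000L, seed = NULL,
                           exposureSd = 1, scale = "per 1-SD") {
  s <- snpSummary[snpSummary$beta_exp != 0, , drop = FALSE]
  if (nrow(s) < 3L) stop("weighted median needs at least 3 SNPs with nonzero exposure associations")
  if (!is.null(seed)) set.seed(seed)
  point <- .wmPoint(s$beta_out / s$beta_exp, s$beta_exp^2 / s$se_out^2)
  boot <- vapply(seq_len(nBoot), function(i) {
    be <- rnorm(nrow(s), s$beta_exp, s$se_exp)
    bo <- rnorm(nrow(s), s$beta_out, s$se_out)
    ok <- be != 0
    .wmPoint(bo[ok] / be[ok], be[ok]^2 / s$se_out[ok]^2)
  }, 0)
  .MrEstimate("weighted_median", scale, point * exposureSd,
              sd(boot) * exposureSd, extras = list(nSnps = nrow(s)))
}

# interpolated weighted median of ratio estimates
.wmPoint <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1L] >= 0.5) return(b[1L])
  j <- which(p >= 0.5)[1L]
  if (is.na(j)) return(b[length(b)])
  b[j - 1L] + (b[j] - b[j - 1L]) * (0.5 - p[j - 1L]) / (p[j] - p[j - 1L])
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect inverse-variance-weighted mean of the per-SNP Wald ratios
#' (equivalently, the zero-intercept weighted regression of outcome on
#' exposure associations). A cross-check companion to the two-stage
#' estimate.
#'
#' @param snpSummary result of [perSnpAssociations()] (>= 2 SNPs retained).
#' @param exposureSd SD of the exposure for per-SD rescaling.
#' @param scale reporting scale recorded on the estimate.
#' @return An [MrEstimate-class] with `nSnps` in `extras`.
#' @export
mrIvw <- function(snpSummary, exposureSd = 1, scale = "per 1-SD") {
  s <- snpSummary[snpSummary$beta_exp != 0, , drop = FALSE]
  if (nrow(s) < 2L) stop("IVW needs at least 2 SNPs with nonzero exposure associations")
  w <- s$beta_exp^2 / s$se_out^2
  est <- sum(w * s$beta_out / s$beta_exp) / sum(w)
  se <- 1 / sqrt(sum(w))
  .MrEstimate("ivw", scale, est * exposureSd, se * exposureSd,
              extras = list(nSnps = nrow(s)))
}

#' Quintiles of the genetic prediction
#'
#' [quintileAnalysis()] applied to the standardized genetic prediction with
#' the MR covariate set, mirroring the observational quintile analysis on
#' the predicted rather than the observed phenotype.
#'
#' @param prediction standardized genetic prediction from [stageOne()].
#' @param followup,event incident outcome.
#' @param covariates MR covariate `data.frame`.
#' @return A [QuintileResult-class].
#' @export
quintilesOfPrediction <- function(prediction, followup, event, covariates) {
  quintileAnalysis(prediction, followup, event, covariates)
}

#' Full two-stage MR for one exposure
#'
#' Aligns a [GrsVector-class] with the cohort on sample id, restricts to
#' complete cases for the exposure and MR covariates, runs [stageOne()],
#' then the incident-case Cox second stage, the all-case logistic
#' robustness model and, when a panel is supplied, the per-SNP
#' pleiotropy-robust estimators (IVW, MR-Egger, weighted median).
#'
#' @param cohort cohort `data.frame` with `sample_id`.
#' @param grs a [GrsVector-class] (names = sample ids).
#' @param exposure name of the exposure column.
#' @param binary is the exposure binary (per-category scale)?
#' @param panel optional complete [GenotypePanel-class] for the per-SNP
#'   estimators.
#' @param estimators subset of `c("two_stage_cox", "two_stage_logistic",
#'   "ivw", "mr_egger", "weighted_median")`.
#' @param nBoot,seed weighted-median bootstrap controls.
#' @return list of class `MrResult`: `stageOne`, `estimates` (named list of
#'   [MrEstimate-class]), `snpSummary` (or `NULL`), `log`.
#' @export
runMr <- function(cohort, grs, exposure, binary = FALSE, panel = NULL,
                  estimators = c("two_stage_cox", "two_stage_logistic",
                                 "ivw", "mr_egger", "weighted_median"),
                  nBoot = 1000L, seed = NULL) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(exposure %in% names(cohort))
  sc <- scores(grs)
  idx <- match(cohort$sample_id, names(sc))
  if (anyNA(idx)) stop("cohort sample ids missing from the GRS")
  cohort$.grs <- unname(sc[idx])
  covars <- covariateModel(cohort, "mr")
  ok <- complete.cases(cohort[[exposure]], covars, cohort$.grs)
  cohort <- cohort[ok, , drop = FALSE]
  covars <- covars[ok, , drop = FALSE]
  log <- if (any(!ok)) paste(sum(!ok), "incomplete case(s) dropped") else character(0)
  # constant covariates (e.g. the stratifier inside a subgroup) carry no
  # information and break the rank check: drop them with a log entry
  constant <- vapply(covars, function(v) length(unique(v)) < 2L, logical(1))
  if (any(constant)) {
    log <- c(log, paste("constant covariate(s) dropped:",
                        paste(names(covars)[constant], collapse = ", ")))
    covars <- covars[, !constant, drop = FALSE]
  }

  s1 <- stageOne(cohort$.grs, cohort[[exposure]], covars, binary = binary)
  inc <- cohort$prevalent == 0L
  estimates <- list()
  if ("two_stage_cox" %in% estimators)
    estimates$two_stage_cox <- stageTwoCox(
      s1$prediction[inc], cohort$followup_years[inc], cohort$event[inc],
      covars[inc, , drop = FALSE], scale = s1$scale, rescale = s1$rescale)
  if ("two_stage_logistic" %in% estimators)
    estimates$two_stage_logistic <- stageTwoLogistic(
      s1$prediction, as.integer(cohort$event == 1L | cohort$prevalent == 1L),
      covars, scale = s1$scale, rescale = s1$rescale)
  snpSummary <- NULL
  perSnp <- intersect(c("ivw", "mr_egger", "weighted_median"), estimators)
  if (length(perSnp)) {
    if (is.null(panel))
      stop("per-SNP estimators (", paste(perSnp, collapse = ", "),
           ") need the genotype panel")
    panel <- panel[, cohort$sample_id[inc]]
    snpSummary <- perSnpAssociations(
      panel, cohort[[exposure]][inc], cohort$followup_years[inc],
      cohort$event[inc], covars[inc, , drop = FALSE])
    expSd <- if (binary) 1 else sd(cohort[[exposure]])
    if ("ivw" %in% perSnp)
      estimates$ivw <- mrIvw(snpSummary, expSd, s1$scale)
    if ("mr_egger" %in% perSnp)
      estimates$mr_egger <- mrEgger(snpSummary, expSd, s1$scale)
    if ("weighted_median" %in% perSnp)
      estimates$weighted_median <- weightedMedian(snpSummary, nBoot, seed,
                                                  expSd, s1$scale)
  }
  for (nm in names(estimates)) estimates[[nm]]@extras$F <- s1$fStat
  structure(list(stageOne = s1, estimates = estimates,
                 snpSummary = snpSummary, sampleIds = cohort$sample_id,
                 log = log),
            class = "MrResult")
}

#' Subgroup MR by sex or age band
#'
#' Re-runs the full two-stage pipeline within each stratum (stage one refit
#' per stratum). Strata with fewer than `minEvents` incident events are
#' skipped with a log entry.
#'
#' @param cohort,grs,exposure,binary,panel,estimators,nBoot,seed as in
#'   [runMr()].
#' @param by `"sex"` or `"age_band"` (age in 10-year bands).
#' @param minEvents minimum incident events per stratum.
#' @return named list of `MrResult`; skipped strata in `attr(, "log")`.
#' @export
subgroupMr <- function(cohort, grs, exposure, by = c("sex", "age_band"),
                       binary = FALSE, panel = NULL,
                       estimators = "two_stage_cox", minEvents = 50L,
                       nBoot = 1000L, seed = NULL) {
  by <- match.arg(by)
  strata <- if (by == "sex") factor(cohort$sex, levels = c(0, 1),
                                    labels = c("male", "female"))
            else factor(10 * floor(cohort$age / 10))
  out <- list()
  log <- character(0)
  for (lev in levels(strata)) {
    sub <- cohort[strata == lev, , drop = FALSE]
    nev <- sum(sub$event[sub$prevalent == 0L])
    if (nrow(sub) == 0L || nev < minEvents) {
      log <- c(log, sprintf("%s=%s: skipped (%d incident events < %d)",
                            by, lev, nev, minEvents))
      next
    }
    out[[lev]] <- runMr(sub, grs, exposure, binary = binary, panel = panel,
                        estimators = estimators, nBoot = nBoot, seed = seed)
  }
  attr(out, "log") <- log
  out
}
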