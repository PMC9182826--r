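#' Replicate a scenario and summarize the estimators per replicate
#'
#' Monte-Carlo driver for operating-characteristic studies (bias, coverage,
#' type-I error, pleiotropy-test size and power): simulates `nReps`
#' independent cohorts from `scenario` (replicate `r` uses seed
#' `seed + r`), builds the GRS from the fabricated weight file, runs the
#' requested estimators through the regular pipeline functions, and returns
#' one row per replicate.
#'
#' @param nReps number of replicates.
#' @param scenario an [MrScenario-class]; its seed slot is overridden per
#'   replicate.
#' @param seed base seed (replicate seeds are `seed + 1 .. seed + nReps`).
#' @param estimators passed to [runMr()]; per-SNP estimators trigger the
#'   per-SNP association fits (the expensive part).
#' @param observational also fit the observational Cox scan on the raw
#'   exposure (per-SD unit) for the confounding contrast?
#' @param nBoot weighted-median bootstrap replicates.
#' @return `data.frame` with one row per replicate; always `f_stat` plus,
#'   per requested piece, `ts_loghr`, `ts_se`, `ts_p`, `ts_covered` (Wald
#'   CI covering the true `causalLogHr`), `logit_logor`, `ivw_loghr`,
#'   `egger_loghr`, `egger_int`, `egger_int_p`, `wm_loghr`, `obs_loghr`,
#'   `obs_se`, `obs_p`, `events`.
#' @examples
#' \donttest{
#' sc <- MrScenario(nSamples = 1500, nSnps = 10, baselineHazard = 0.01,
#'                  missingRate = 0, prevalentRate = 0)
#' simulationStudy(3, sc, seed = 9)
#' }
#' @export
simulationStudy <- function(nReps, scenario, seed = 1L,
                            estimators = "two_stage_cox",
                            observational = FALSE, nBoot = 200L) {
  theta <- scenario@causalLogHr
  perSnp <- any(c("ivw", "mr_egger", "weighted_median") %in% estimators)
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    sc <- scenario
    sc@seed <- as.integer(seed + r)
    sim <- simulateCohort(sc)
    cohort <- cohortData(sim$panel)
    panel <- if (scenario@missingRate > 0) imputeMissing(sim$panel)
             else sim$panel
    grs <- computeGrs(panel, sim$weights)
    res <- runMr(cohort, grs, "exposure_sim",
                 binary = scenario@binaryExposure,
                 panel = if (perSnp) panel else NULL,
                 estimators = estimators, nBoot = nBoot, seed = sc@seed)
    row <- list(rep = r, f_stat = res$stageOne$fStat,
                events = sum(cohort$event[cohort$prevalent == 0]))
    ts <- res$estimates$two_stage_cox
    if (!is.null(ts)) {
      row$ts_loghr <- ts@logEstimate
      row$ts_se <- ts@se
      row$ts_p <- ts@p
      row$ts_covered <- (ts@logEstimate - 1.96 * ts@se <= theta) &&
                        (theta <= ts@logEstimate + 1.96 * ts@se)
    }
    lg <- res$estimates$two_stage_logistic
    if (!is.null(lg)) row$logit_logor <- lg@logEstimate
    iv <- res$estimates$ivw
    if (!is.null(iv)) row$ivw_loghr <- iv@logEstimate
    eg <- res$estimates$mr_egger
    if (!is.null(eg)) {
      row$egger_loghr <- eg@logEstimate
      row$egger_int <- eg@extras$intercept
      row$egger_int_p <- eg@extras$interceptP
    }
    wm <- res$estimates$weighted_median
    if (!is.null(wm)) row$wm_loghr <- wm@logEstimate
    if (observational) {
      scan <- runExposureScan(cohort,
                              exposureSpec("exposure_sim", unit = 1,
                                           model = "observational"),
                              k = 1)
      sdx <- sd(cohort$exposure_sim[cohort$prevalent == 0])
      row$obs_loghr <- log(scan$hr) * sdx
      row$obs_se <- (log(scan$ci_high) - log(scan$hr)) / 1.96 * sdx
      row$obs_p <- scan$p
    }
    rows[[r]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}

#' Preset simulation designs for operating-characteristic studies
#'
#' Fixed study conditions used by the package's own evaluation (and its
#' acceptance checks): a desk-scale confounded cohort for parameter
#' recovery (`"recovery"`), its null-effect counterpart for type-I error
#' and the confounding contrast (`"null"`), a clean-instrument design for
#' the size of the Egger intercept test (`"egger_null"`), a
#' strong-instrument common-outcome design powered (by an a priori
#' power analysis of the intercept test) to detect directional pleiotropy
#' calibrated to ~30% of the instrument-outcome signal
#' (`"egger_directional"`), and a 30%-invalid-instrument design for the
#' weighted-median robustness contrast (`"invalid_instruments"`).
#'
#' @param design preset name.
#' @return An [MrScenario-class].
#' @export
studyScenario <- function(design = c("recovery", "null", "egger_null",
                                     "egger_directional",
                                     "invalid_instruments")) {
  design <- match.arg(design)
  base <- list(nSnps = 30, instrumentR2 = 0.05,
               confounderEffectExposure = 0.5, confounderLogHr = 0.5,
               causalLogHr = log(1.2), missingRate = 0, prevalentRate = 0)
  args <- switch(design,
    recovery = c(base, nSamples = 5000, baselineHazard = 0.006),
    null = c(modifyList(base, list(causalLogHr = 0)),
             nSamples = 5000, baselineHazard = 0.006),
    egger_null = c(base, nSamples = 1500, baselineHazard = 0.03),
    egger_directional = {
      # directional pleiotropy worth ~30% of the per-SNP instrument-outcome
      # signal theta * gamma_bar, with gamma_bar = sqrt(R2 / (m E[2pq])).
      # Intercept precision scales with the event count, so this design
      # uses a strong instrument and a common outcome, and omits the latent
      # confounder: its hazard-side variance would otherwise attenuate all
      # marginal per-SNP log-HRs (non-collapsibility) and with them the
      # realized intercept.
      r2 <- 0.30; m <- 30
      e2pq <- 2 * (0.5 - (0.3^2 + 0.3 * 0.7 + 0.7^2) / 3)
      mu <- (0.3 / 0.7) * log(1.2) * sqrt(r2 / (m * e2pq))
      c(modifyList(base, list(instrumentR2 = r2,
                              confounderEffectExposure = 0,
                              confounderLogHr = 0)),
        nSamples = 40000, baselineHazard = 0.15,
        eafRange = list(c(0.3, 0.7)),
        pleiotropyMean = mu, pleiotropySd = mu / 4)
    },
    invalid_instruments = c(base, nSamples = 6000, baselineHazard = 0.2,
                            pleiotropyMean = 0.08, pleiotropySd = 0.02,
                            pleiotropyFraction = 0.3))
  do.call(MrScenario, args)
}
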