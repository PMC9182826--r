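#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats lm glm coef qnorm pnorm plogis qlogis rnorm runif rbinom
#'   rexp quantile sd var cor median complete.cases model.matrix binomial
#'   setNames pchisq pt weighted.mean
#' @importFrom utils write.table read.table packageVersion modifyList
NULL

#' Simulation scenario for a synthetic one-sample MR cohort
#'
#' An `MrScenario` bundles every knob of the synthetic-cohort generator:
#' cohort and instrument dimensions, allele frequencies, LD structure,
#' instrument strength, latent confounding, directional pleiotropy, the true
#' causal log hazard ratio, and the censoring scheme. The generator's
#' ground truth (per-SNP effects actually used) is returned alongside the
#' data so that downstream estimators can be tested for parameter recovery.
#'
#' @slot nSamples number of participants.
#' @slot nSnps number of instrument SNPs.
#' @slot eafRange range of effect-allele frequencies, drawn uniformly.
#' @slot ldBlockSize SNPs per LD block (1 = independent SNPs).
#' @slot ldRho latent Gaussian-copula correlation within an LD block, in \[0,1).
#' @slot missingRate proportion of dosage cells set missing in the analysis copy.
#' @slot instrumentR2 proportion of exposure variance jointly explained by SNPs.
#' @slot confounderEffectExposure effect of the latent confounder U (per SD of
#'   U) on the standardized exposure.
#' @slot confounderLogHr effect of U on the log hazard.
#' @slot causalLogHr true causal log hazard ratio per 1-SD exposure.
#' @slot pleiotropyMean,pleiotropySd mean and SD of per-SNP direct effects on
#'   the log hazard; a nonzero mean encodes directional pleiotropy.
#' @slot pleiotropyFraction fraction of SNPs receiving a direct effect
#'   (1 = all; 0.3 emulates a 30%-invalid instrument set, the regime the
#'   weighted-median estimator is designed for).
#' @slot baselineHazard constant baseline hazard rate, per year.
#' @slot adminCensorYears administrative censoring horizon (years from the
#'   start of recruitment).
#' @slot entryWindowYears recruitment window; entry times are uniform on
#'   \[0, entryWindowYears\] so censoring times are
#'   `adminCensorYears - entry`.
#' @slot prevalentRate expected fraction flagged as prevalent cases at baseline.
#' @slot binaryExposure if `TRUE` the exposure is dichotomized at the
#'   liability threshold matching `binaryPrevalence`.
#' @slot binaryPrevalence target prevalence of the binary exposure.
#' @slot seed integer seed; one global seed drives all sub-streams.
#'
#' @details Defaults emulate a desk-scale version of a large prospective
#' biobank cohort: recruitment ages 40--69, mean follow-up 8.4 (SD 1.6)
#' years, a rare incident outcome (cumulative incidence about 0.4%), a
#' 30-SNP instrument explaining 5% of exposure variance, and a latent
#' confounder acting on both exposure and hazard.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("MrScenario",
  representation(
    nSamples = "integer", nSnps = "integer",
    eafRange = "numeric", ldBlockSize = "integer", ldRho = "numeric",
    missingRate = "numeric", instrumentR2 = "numeric",
    confounderEffectExposure = "numeric", confounderLogHr = "numeric",
    causalLogHr = "numeric", pleiotropyMean = "numeric",
    pleiotropySd = "numeric", pleiotropyFraction = "numeric",
    baselineHazard = "numeric",
    adminCensorYears = "numeric", entryWindowYears = "numeric",
    prevalentRate = "numeric", binaryExposure = "logical",
    binaryPrevalence = "numeric", seed = "integer"
  ),
  prototype(
    nSamples = 20000L, nSnps = 30L,
    eafRange = c(0.05, 0.95), ldBlockSize = 1L, ldRho = 0,
    missingRate = 0.02, instrumentR2 = 0.05,
    confounderEffectExposure = 0.5, confounderLogHr = 0.5,
    causalLogHr = log(1.2), pleiotropyMean = 0, pleiotropySd = 0,
    pleiotropyFraction = 1, baselineHazard = 5.3e-4, adminCensorYears = 11.2,
    entryWindowYears = 5.5, prevalentRate = 0.003,
    binaryExposure = FALSE, binaryPrevalence = 0.25, seed = 1L
  )
)

setValidity("MrScenario", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@nSamples >= 1L, "nSamples must be >= 1")
  chk(object@nSnps >= 1L, "nSnps must be >= 1")
  chk(length(object@eafRange) == 2L && all(object@eafRange > 0) &&
        all(object@eafRange < 1) && object@eafRange[1] <= object@eafRange[2],
      "eafRange must be an increasing pair inside (0,1)")
  chk(object@ldBlockSize >= 1L, "ldBlockSize must be >= 1")
  chk(object@ldRho >= 0 && object@ldRho < 1, "ldRho must be in [0,1)")
  chk(object@missingRate >= 0 && object@missingRate < 1,
      "missingRate must be in [0,1)")
  chk(object@instrumentR2 >= 0 && object@instrumentR2 < 1,
      "instrumentR2 must be in [0,1)")
  chk(object@pleiotropyFraction >= 0 && object@pleiotropyFraction <= 1,
      "pleiotropyFraction must be in [0,1]")
  chk(object@instrumentR2 + object@confounderEffectExposure^2 <= 1,
      "instrumentR2 + confounderEffectExposure^2 exceeds 1: residual exposure variance would be negative")
  chk(object@baselineHazard > 0, "baselineHazard must be > 0")
  chk(object@adminCensorYears > 0, "adminCensorYears must be > 0")
  chk(object@entryWindowYears >= 0 &&
        object@entryWindowYears < object@adminCensorYears,
      "entryWindowYears must be in [0, adminCensorYears)")
  chk(object@prevalentRate >= 0 && object@prevalentRate < 1,
      "prevalentRate must be in [0,1)")
  chk(object@binaryPrevalence > 0 && object@binaryPrevalence < 1,
      "binaryPrevalence must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation scenario
#'
#' @param nSamples,nSnps cohort and instrument dimensions.
#' @param eafRange,ldBlockSize,ldRho,missingRate genotype-panel knobs.
#' @param instrumentR2,confounderEffectExposure,confounderLogHr,causalLogHr,pleiotropyMean,pleiotropySd,pleiotropyFraction
#'   structural parameters of the exposure/outcome model.
#' @param baselineHazard,adminCensorYears,entryWindowYears,prevalentRate
#'   survival and case-mix knobs.
#' @param binaryExposure,binaryPrevalence liability-threshold dichotomization.
#' @param seed global integer seed.
#' @return A validated [MrScenario-class] object.
#' @examples
#' sc <- MrScenario(nSamples = 1000, nSnps = 10, seed = 7)
#' sc
#' @export
MrScenario <- function(nSamples = 20000, nSnps = 30,
                       eafRange = c(0.05, 0.95), ldBlockSize = 1, ldRho = 0,
                       missingRate = 0.02, instrumentR2 = 0.05,
                       confounderEffectExposure = 0.5, confounderLogHr = 0.5,
                       causalLogHr = log(1.2), pleiotropyMean = 0,
                       pleiotropySd = 0, pleiotropyFraction = 1,
                       baselineHazard = 5.3e-4,
                       adminCensorYears = 11.2, entryWindowYears = 5.5,
                       prevalentRate = 0.003, binaryExposure = FALSE,
                       binaryPrevalence = 0.25, seed = 1) {
  new("MrScenario",
      nSamples = as.integer(nSamples), nSnps = as.integer(nSnps),
      eafRange = as.numeric(eafRange), ldBlockSize = as.integer(ldBlockSize),
      ldRho = as.numeric(ldRho), missingRate = as.numeric(missingRate),
      instrumentR2 = as.numeric(instrumentR2),
      confounderEffectExposure = as.numeric(confounderEffectExposure),
      confounderLogHr = as.numeric(confounderLogHr),
      causalLogHr = as.numeric(causalLogHr),
      pleiotropyMean = as.numeric(pleiotropyMean),
      pleiotropySd = as.numeric(pleiotropySd),
      pleiotropyFraction = as.numeric(pleiotropyFraction),
      baselineHazard = as.numeric(baselineHazard),
      adminCensorYears = as.numeric(adminCensorYears),
      entryWindowYears = as.numeric(entryWindowYears),
      prevalentRate = as.numeric(prevalentRate),
      binaryExposure = isTRUE(binaryExposure),
      binaryPrevalence = as.numeric(binaryPrevalence),
      seed = as.integer(seed))
}

#' Ground truth of a simulated cohort
#'
#' Stores the per-SNP exposure effects, per-SNP direct (pleiotropic) outcome
#' effects, the causal log hazard ratio and the confounder effects exactly as
#' used during generation, together with the latent confounder values. This
#' enables parameter-recovery tests; analysis code never sees it.
#'
#' @slot gamma named per-SNP effects on the exposure.
#' @slot alpha named per-SNP direct effects on the log hazard.
#' @slot theta true causal log hazard ratio per exposure unit.
#' @slot confounderEffectExposure,confounderLogHr confounder effects used.
#' @slot u latent confounder values (length `nSamples`).
#' @slot liability continuous liability underlying a binary exposure
#'   (length 0 for continuous exposures).
#' @export
setClass("GroundTruth",
  representation(gamma = "numeric", alpha = "numeric", theta = "numeric",
                 confounderEffectExposure = "numeric",
                 confounderLogHr = "numeric", u = "numeric",
                 liability = "numeric"))

#' Genotype dosage panel with SNP weights and cohort covariates
#'
#' `GenotypePanel` extends [SummarizedExperiment::SummarizedExperiment] with
#' one assay, `"dosage"`: a SNPs x samples matrix of effect-allele dosages in
#' \[0,2\], `NA` where missing. `rowData` carries the per-SNP GWAS weight
#' record (`effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`);
#' `colData` carries the per-participant cohort table (covariates, exposures,
#' follow-up, event indicators).
#'
#' @seealso [dosages()], [missingMask()], [snpWeights()], [cohortData()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    rng <- suppressWarnings(range(d, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      msg <- c(msg, "non-missing dosages must lie in [0,2]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a genotype panel
#'
#' @param dosage SNPs x samples numeric matrix of dosages in \[0,2\], `NA`
#'   for missing. Row names are SNP ids, column names sample ids.
#' @param snpInfo `data.frame` of per-SNP metadata (one row per SNP), e.g.
#'   the GWAS weight fields. Optional.
#' @param sampleInfo `data.frame` of per-sample covariates. Optional.
#' @return A [GenotypePanel-class].
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' GenotypePanel(d)
#' @export
GenotypePanel <- function(dosage, snpInfo = NULL, sampleInfo = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("rs", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("id", seq_len(ncol(dosage)))
  rd <- if (is.null(snpInfo)) S4Vectors::DataFrame(row.names = rownames(dosage))
        else S4Vectors::DataFrame(snpInfo, row.names = rownames(dosage))
  cd <- if (is.null(sampleInfo)) S4Vectors::DataFrame(row.names = colnames(dosage))
        else S4Vectors::DataFrame(sampleInfo, row.names = colnames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("GenotypePanel", se)
}

#' Per-sample weighted genetic risk score
#'
#' Holds the scores together with their provenance: which SNPs were retained
#' with which weights, and a log of filtering, pruning, harmonization and
#' imputation actions.
#'
#' @slot score named numeric vector, one score per sample.
#' @slot snps `data.frame` of retained SNPs and the weights used.
#' @slot log character vector of provenance messages.
#' @export
setClass("GrsVector",
  representation(score = "numeric", snps = "data.frame", log = "character"))

setValidity("GrsVector", function(object) {
  if (length(object@score) && any(!is.finite(object@score)))
    "scores must be finite for all samples" else TRUE
})

#' Mendelian-randomization estimate
#'
#' One causal-effect estimate with its uncertainty and diagnostics, on the
#' ratio scale the second-stage model reports (hazard ratio for Cox, odds
#' ratio for logistic).
#'
#' @slot estimator one of `two_stage_cox`, `two_stage_logistic`, `ivw`,
#'   `mr_egger`, `weighted_median`.
#' @slot scale reporting scale, e.g. `"per 1-SD"` or `"per category"`.
#' @slot logEstimate,se point estimate and standard error on the log scale.
#' @slot ciLow,ciHigh 95% confidence bounds on the ratio scale
#'   (`exp(logEstimate -/+ 1.96 se)`).
#' @slot p two-sided p-value.
#' @slot n,events analysis sample size and event count (NA where undefined).
#' @slot extras list of estimator-specific diagnostics (Egger intercept and
#'   its SE/p, F-statistic, per-SNP counts, ...).
#' @export
setClass("MrEstimate",
  representation(estimator = "character", scale = "character",
                 logEstimate = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                 n = "numeric", events = "numeric", extras = "list"))

setValidity("MrEstimate", function(object) {
  msg <- character()
  est <- exp(object@logEstimate)
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      !(object@ciLow <= est + 1e-12 && est <= object@ciHigh + 1e-12))
    msg <- c(msg, "ciLow <= estimate <= ciHigh must hold")
  if (!length(object@scale) || !nzchar(object@scale))
    msg <- c(msg, "scale must be recorded, never implicit")
  if (length(msg)) msg else TRUE
})

.MrEstimate <- function(estimator, scale, logEstimate, se, n = NA_real_,
                        events = NA_real_, extras = list()) {
  z <- logEstimate / se
  new("MrEstimate", estimator = estimator, scale = scale,
      logEstimate = logEstimate, se = se,
      ciLow = exp(logEstimate - 1.96 * se),
      ciHigh = exp(logEstimate + 1.96 * se),
      p = 2 * pnorm(-abs(z)), n = as.numeric(n), events = as.numeric(events),
      extras = extras)
}

#' Quintile dose-response result
#'
#' Equal-frequency fifths of an exposure (or of a genetic prediction), with
#' per-group hazard ratios against the bottom fifth and an
#' inverse-variance-weighted log-linear trend.
#'
#' @slot cutPoints the four interior cut points.
#' @slot groups `data.frame` with one row per fifth: `group`, `n`, `events`,
#'   `median` (median exposure), `logHr`, `se`, `hr`, `ciLow`, `ciHigh`.
#'   The reference group has `hr` exactly 1 and `NA` bounds.
#' @slot reference index of the reference group (1 = lowest fifth).
#' @slot trendSlope,trendSe inverse-variance-weighted trend of log HR on
#'   group median exposure.
#' @export
setClass("QuintileResult",
  representation(cutPoints = "numeric", groups = "data.frame",
                 reference = "integer", trendSlope = "numeric",
                 trendSe = "numeric"))

setValidity("QuintileResult", function(object) {
  msg <- character()
  g <- object@groups
  if (nrow(g)) {
    if (abs(g$hr[object@reference] - 1) > 1e-12)
      msg <- c(msg, "reference group HR must be exactly 1")
    if (diff(range(g$n)) > 1)
      msg <- c(msg, "group sizes must differ by at most 1")
  }
  if (length(msg)) msg else TRUE
})
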