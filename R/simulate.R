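#' Simulate a genotype dosage panel
#'
#' Draws effect-allele dosages per SNP as Binomial(2, EAF) under
#' Hardy-Weinberg equilibrium. Within an LD block the two latent allele
#' draws per person are generated from a Gaussian copula with exchangeable
#' correlation `ldRho`, which yields tunable positive dosage correlation
#' while preserving the marginal binomial distribution. A fraction
#' `missingRate` of cells is set missing uniformly at random.
#'
#' @param scenario an [MrScenario-class].
#' @param withMissingness impose the scenario's missingness on the returned
#'   panel? [simulateCohort()] generates phenotypes from the complete matrix
#'   and imposes missingness only on the analysis copy at the end.
#' @return A [GenotypePanel-class]; `rowData` carries `eaf_true`, the
#'   frequencies used.
#' @examples
#' p <- simulateGenotypes(MrScenario(nSamples = 100, nSnps = 5, seed = 3))
#' dim(dosages(p))
#' @export
simulateGenotypes <- function(scenario, withMissingness = TRUE) {
  validObject(scenario)
  n <- scenario@nSamples
  m <- scenario@nSnps
  eaf <- runif(m, scenario@eafRange[1], scenario@eafRange[2])
  dose <- .drawHaplotype(n, eaf, scenario@ldBlockSize, scenario@ldRho) +
          .drawHaplotype(n, eaf, scenario@ldBlockSize, scenario@ldRho)
  dose <- t(dose)  # SNPs x samples
  dimnames(dose) <- list(paste0("rs", seq_len(m)),
                         sprintf("id%06d", seq_len(n)))
  if (withMissingness && scenario@missingRate > 0)
    dose[matrix(runif(m * n) < scenario@missingRate, m, n)] <- NA_real_
  GenotypePanel(dose, snpInfo = data.frame(eaf_true = eaf))
}

# one haplotype: latent exchangeable-correlation normals thresholded at
# qnorm(eaf); returns samples x SNPs 0/1 matrix
.drawHaplotype <- function(n, eaf, blockSize, rho) {
  m <- length(eaf)
  if (rho == 0 || blockSize == 1L) {
    z <- matrix(rnorm(n * m), n, m)
  } else {
    block <- rep(seq_len(ceiling(m / blockSize)), each = blockSize)[seq_len(m)]
    w <- matrix(rnorm(n * max(block)), n, max(block))
    z <- sqrt(rho) * w[, block, drop = FALSE] +
         sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
  }
  (z < rep(qnorm(eaf), each = n)) + 0
}

#' Impose missingness on a panel's analysis copy
#'
#' @param panel a [GenotypePanel-class].
#' @param missingRate proportion of cells set to `NA` uniformly at random.
#' @return The panel with missing cells.
#' @export
applyMissingness <- function(panel, missingRate) {
  stopifnot(missingRate >= 0, missingRate < 1)
  d <- dosages(panel)
  d[matrix(runif(length(d)) < missingRate, nrow(d), ncol(d))] <- NA_real_
  SummarizedExperiment::assay(panel, "dosage") <- d
  panel
}

#' Simulate an exposure driven by genotypes and a latent confounder
#'
#' The continuous exposure is `x = sum_j gamma_j g_j + b U + eps`, with the
#' per-SNP effects `gamma_j` drawn with spread and rescaled so the SNPs
#' jointly explain exactly `instrumentR2` of the (unit) exposure variance in
#' the generated sample; `U` is a standard-normal latent confounder with
#' coefficient `b = confounderEffectExposure`, and the residual variance is
#' `1 - instrumentR2 - b^2` (an invalid decomposition is rejected at
#' scenario validation). For a binary exposure the continuous value is kept
#' as the liability and dichotomized at the threshold matching
#' `binaryPrevalence`.
#'
#' @param panel a complete (no missing dosages) [GenotypePanel-class].
#' @param scenario an [MrScenario-class].
#' @return list with `exposure` (numeric per sample) and `truth`
#'   (a [GroundTruth-class]; `alpha` is filled in by [simulateSurvival()]).
#' @export
simulateExposure <- function(panel, scenario) {
  g <- dosages(panel)
  if (anyNA(g))
    stop("exposure generation requires the complete dosage matrix; impose missingness afterwards")
  n <- ncol(g)
  m <- nrow(g)
  r2 <- scenario@instrumentR2
  b <- scenario@confounderEffectExposure
  if (r2 + b^2 > 1)
    stop("invalid scenario: instrumentR2 + confounder variance exceed 1")
  if (r2 > 0) {
    gammaRaw <- runif(m, 0.2, 1.8)  # spread keeps Egger's intercept identified
    s <- as.numeric(crossprod(g, gammaRaw))
    if (sd(s) == 0) stop("degenerate genotypes: genetic score has zero variance")
    gamma <- gammaRaw * sqrt(r2) / sd(s)
    s <- s * sqrt(r2) / sd(s)
  } else {
    gamma <- rep(0, m)
    s <- rep(0, n)
  }
  u <- rnorm(n)
  x <- s + b * u + sqrt(1 - r2 - b^2) * rnorm(n)
  liability <- numeric(0)
  if (scenario@binaryExposure) {
    liability <- x
    thr <- mean(s) + qnorm(1 - scenario@binaryPrevalence)
    x <- as.numeric(x > thr)
  }
  truth <- new("GroundTruth",
               gamma = setNames(gamma, rownames(g)), alpha = numeric(0),
               theta = scenario@causalLogHr,
               confounderEffectExposure = b,
               confounderLogHr = scenario@confounderLogHr,
               u = u, liability = liability)
  list(exposure = x, truth = truth)
}

#' Simulate incident event times under exact proportional hazards
#'
#' Event times are exponential with hazard
#' `h0 * exp(theta x + c U + sum_j alpha_j g_j)`, so the proportional-hazards
#' assumption holds exactly. Entry times are uniform over the recruitment
#' window and follow-up is administratively censored at
#' `adminCensorYears - entry`. Per-SNP direct effects `alpha_j` are drawn
#' from `N(pleiotropyMean, pleiotropySd)`; a nonzero mean encodes
#' directional horizontal pleiotropy. A `prevalentRate` fraction is flagged
#' as prevalent baseline cases, drawn with probability increasing in the
#' same linear predictor so the logistic robustness model sees signal.
#'
#' @param panel complete [GenotypePanel-class] (generation copy).
#' @param exposure numeric exposure per sample.
#' @param scenario an [MrScenario-class].
#' @param truth the [GroundTruth-class] from [simulateExposure()] (supplies
#'   the confounder values).
#' @return list with `survival` (`data.frame` of `followup_years`, `event`,
#'   `prevalent`) and the completed `truth`.
#' @export
simulateSurvival <- function(panel, exposure, scenario, truth) {
  if (scenario@baselineHazard <= 0) stop("baseline hazard must be positive")
  g <- dosages(panel)
  if (anyNA(g)) stop("survival generation requires the complete dosage matrix")
  n <- ncol(g)
  m <- nrow(g)
  alpha <- if (scenario@pleiotropyMean == 0 && scenario@pleiotropySd == 0)
    rep(0, m) else rnorm(m, scenario@pleiotropyMean, scenario@pleiotropySd)
  if (scenario@pleiotropyFraction < 1 && any(alpha != 0)) {
    # only a fixed fraction of instruments is invalid; the rest stay clean
    nInvalid <- round(scenario@pleiotropyFraction * m)
    valid <- setdiff(seq_len(m), sample.int(m, nInvalid))
    alpha[valid] <- 0
  }
  lp <- scenario@causalLogHr * exposure + scenario@confounderLogHr * truth@u +
        as.numeric(crossprod(g, alpha))
  eventTime <- rexp(n) / (scenario@baselineHazard * exp(lp))
  entry <- runif(n, 0, scenario@entryWindowYears)
  censorTime <- scenario@adminCensorYears - entry
  followup <- pmin(eventTime, censorTime)
  event <- as.integer(eventTime <= censorTime)
  prevalent <- if (scenario@prevalentRate > 0)
    rbinom(n, 1L, plogis(qlogis(scenario@prevalentRate) + lp - mean(lp)))
  else rep(0L, n)
  truth@alpha <- setNames(alpha, rownames(g))
  list(survival = data.frame(followup_years = followup, event = event,
                             prevalent = prevalent),
       truth = truth)
}

#' Simulate baseline covariates
#'
#' Covariates of the MR adjustment set (sex, age uniform on \[40, 69\], ten
#' standard-normal genetic principal components, genotyping-chip indicator)
#' plus stand-in columns for the observational adjustment set (family
#' history, education and income categories, Townsend index, physical
#' activity METs, alcohol, smoking status, systolic blood pressure,
#' lipid-lowering medication). Stand-ins are generated independently of the
#' exposure and outcome.
#'
#' @param scenario an [MrScenario-class].
#' @return `data.frame` with one row per sample.
#' @export
simulateCovariates <- function(scenario) {
  n <- scenario@nSamples
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  data.frame(
    sex = rbinom(n, 1L, 0.5),             # 1 = female
    age = runif(n, 40, 69),
    pcs,
    chip = rbinom(n, 1L, 0.5),
    family_history = rbinom(n, 1L, 0.6),
    education = sample.int(6L, n, replace = TRUE),
    income = sample.int(5L, n, replace = TRUE),
    townsend = rnorm(n),
    mets = pmax(rnorm(n, 30, 15), 0),
    alcohol = pmax(rnorm(n, 10, 8), 0),
    smoking_status = sample(0:2, n, replace = TRUE, prob = c(0.55, 0.34, 0.11)),
    sbp = rnorm(n, 140.1, 19.6),
    lipid_med = rbinom(n, 1L, 0.17))
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Orchestrates [simulateGenotypes()], [simulateCovariates()],
#' [simulateExposure()] and [simulateSurvival()] under one global seed,
#' generating phenotypes from the complete dosage matrix and imposing
#' missingness only on the returned analysis panel. Also fabricates the
#' GWAS weight file for the instruments: `beta` is the true per-SNP exposure
#' effect, with standard errors of a large (n = 250,000) source GWAS and the
#' implied p-values.
#'
#' @param scenario an [MrScenario-class].
#' @return list with
#'   \describe{
#'     \item{panel}{[GenotypePanel-class]; `colData` holds the cohort table
#'       (covariates, `exposure_sim`, `followup_years`, `event`,
#'       `prevalent`), `rowData` the weight fields.}
#'     \item{weights}{the GWAS weight `data.frame`
#'       (`snp_id effect_allele other_allele beta se pvalue eaf`).}
#'     \item{truth}{[GroundTruth-class] used in generation.}
#'   }
#' @examples
#' sim <- simulateCohort(MrScenario(nSamples = 500, nSnps = 5, seed = 11))
#' sim$panel
#' @export
simulateCohort <- function(scenario) {
  validObject(scenario)
  set.seed(scenario@seed)
  panel <- simulateGenotypes(scenario, withMissingness = FALSE)
  covars <- simulateCovariates(scenario)
  expo <- simulateExposure(panel, scenario)
  surv <- simulateSurvival(panel, expo$exposure, scenario, expo$truth)
  truth <- surv$truth

  eaf <- snpWeights(panel)$eaf_true
  m <- scenario@nSnps
  pairPool <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  alleles <- pairPool[sample.int(4L, m, replace = TRUE)]
  nGwas <- 250000
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * nGwas)
  beta <- unname(truth@gamma)
  weights <- data.frame(
    snp_id = rownames(panel),
    effect_allele = vapply(alleles, `[`, "", 1L),
    other_allele = vapply(alleles, `[`, "", 2L),
    beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta) / se), .Machine$double.xmin),
    eaf = eaf, stringsAsFactors = FALSE)

  cohort <- cbind(covars,
                  exposure_sim = expo$exposure,
                  surv$survival)
  rowInfo <- weights[, c("effect_allele", "other_allele", "beta", "se",
                         "pvalue", "eaf")]
  rownames(rowInfo) <- weights$snp_id
  outPanel <- GenotypePanel(dosages(panel), snpInfo = rowInfo,
                            sampleInfo = cohort)
  if (scenario@missingRate > 0)
    outPanel <- applyMissingness(outPanel, scenario@missingRate)
  list(panel = outPanel, weights = weights, truth = truth)
}
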