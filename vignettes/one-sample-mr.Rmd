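---
title: "One-sample Mendelian randomization with weighted GRS and survival outcomes: methods"
author: "grsMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample MR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Observational associations between modifiable risk factors (adiposity,
lipids, blood pressure, sleep, ...) and an incident disease such as aortic
valve stenosis are vulnerable to confounding and reverse causation.
One-sample Mendelian randomization (MR) treats genetic variants — randomly
assorted at conception and fixed thereafter — as instrumental variables for
the exposure, measured in the same cohort as the time-to-event outcome. If
a variant affects the outcome only through the exposure (no horizontal
pleiotropy), the genetically predicted part of the exposure is free of
confounding, and a two-stage regression estimates the causal effect.

grsMR implements that workflow end to end, together with an observational
Cox scan for contrast, and a synthetic-cohort generator with known ground
truth so that every estimator can be validated by simulation.

## The weighted genetic risk score

For instruments $j = 1..n$ with GWAS effect sizes $\beta_j$ (per effect
allele, in the source GWAS's exposure units) and dosages $g_j \in [0,2]$,

$$\mathrm{GRS} = \frac{\beta_1 g_1 + \cdots + \beta_n g_n}
                     {(\beta_1 + \cdots + \beta_n)/n},$$

the $\beta$-weighted allele count normalized by the mean effect size, so
that equal weights reduce the score to the raw risk-allele count.
Construction applies, in order: the genome-wide significance filter
($p < 5\times10^{-8}$), allele harmonization against the panel (dosage
$g \to 2-g$ for swapped alleles; strand-ambiguous A/T and C/G variants
dropped), greedy LD pruning, and per-SNP mean imputation of missing
dosages.

Design points that the defining formula leaves open:

* **LD statistic.** The pruning threshold of 0.1 is read as squared
  Pearson correlation $r^2$ of sample dosages ($r^2$ is the conventional
  LD scale, and sample dosages are what individual-level data support).
  Pruning visits SNPs in ascending GWAS p-value and keeps a SNP only if
  its $r^2$ with every already-kept SNP is at or below the threshold, so
  the strongest signal per clump survives.
* **Signed denominator.** The normalizing denominator uses signed betas
  exactly as defined. With mixed-sign weights it can approach zero, in
  which case `computeGrs()` raises an error rather than returning an
  exploded score; `useAbsoluteWeights = TRUE` switches to the common
  $|\beta|$ practice.
* **Imputation.** Means are computed within the analysis sample (not from
  the reported allele frequency), and imputation never alters observed
  values.

## Two-stage estimation with a Cox second stage

Stage one regresses the phenotype on the GRS and the instrument-analysis
covariates (sex, age, the first ten genetic principal components,
genotyping chip). The genetic prediction is the fitted genetic component
$\hat\gamma\,\mathrm{GRS}$, z-standardized on the analysis sample. Stage
two fits a Cox proportional-hazards model of the incident outcome on that
standardized prediction plus the same covariates; a logistic model on all
cases (incident plus prevalent) provides a robustness check on the
odds-ratio scale.

**Reporting scale.** In two-stage least squares the *fitted value* carries
the exposure's units: the second-stage coefficient on the unstandardized
prediction estimates the causal log HR per exposure unit. The coefficient
on the z-scored prediction is therefore that effect times the prediction's
SD — a quantity that shrinks with instrument strength and is not what
"per 1-SD higher exposure" means. grsMR keeps the z-scored prediction as
the analysis variable (its mean-0/SD-1 normalization is convenient and
exactly testable) and multiplies the coefficient and its SE by
`exposureSd / predictionSd`, so every reported estimate is the hazard
ratio per 1 SD of the exposure. For a binary exposure, stage one is a
linear probability model, the prediction stays on the probability scale,
and the effect is reported "per category" (a switch standardizes it
instead, for sensitivity).

**Standard errors** are the naive second-stage ones: no correction for
first-stage estimation, the usual choice in one-sample GRS analyses with
strong instruments (first-stage F far above the conventional weak-
instrument bound of 10; grsMR warns below it but never drops an
exposure). The simulation studies below measure the resulting CI coverage
rather than assuming it.

## Pleiotropy-robust sensitivity estimators

Per-SNP summaries feed three estimators, all adjusted for the same
covariate set on both sides, so every slope is on the log-HR scale:

* **IVW**: the inverse-variance-weighted mean of the per-SNP Wald ratios
  $\hat\beta_{out,j}/\hat\beta_{exp,j}$ (fixed-effect weights
  $\beta_{exp,j}^2/\mathrm{se}_{out,j}^2$) — a cross-check that agrees
  with the two-stage estimate when instruments are valid.
* **MR-Egger**: the weighted regression of outcome on exposure
  associations with a free intercept, after orienting all SNPs to
  positive exposure effects. The intercept estimates the average direct
  (pleiotropic) effect; its two-sided p-value, taken from the weighted
  regression t-test, is the directional-pleiotropy diagnostic. Estimating
  the residual dispersion (rather than fixing it at 1) makes the
  intercept test exactly t-calibrated under clean instruments.
* **Weighted median**: the interpolated weighted median of the Wald
  ratios, consistent while valid instruments carry more than half the
  weight; its SE comes from a parametric bootstrap (default 1,000
  replicates under a fixed seed) resampling the per-SNP associations from
  their normal sampling distributions.

## Observational scan, quintiles, subgroups

The observational arm fits one Cox model per exposure under a declared
adjustment set (sex, 5-year age bands, family history, education, income,
Townsend deprivation, METs, alcohol, smoking status, systolic blood
pressure; plus lipid-lowering medication for lipid exposures), rescales
the HR to each exposure's reporting unit
($\mathrm{HR}_u = e^{u\,\hat\beta}$), tests the proportional-hazards
assumption by the Grambsch–Therneau scaled-Schoenfeld score test
(Kaplan–Meier time transform), and flags significance at $\alpha$ and at
the Bonferroni level $\alpha/k$. With $\alpha = 0.05$ and $k = 28$
exposures the corrected threshold is $0.05/28 = 0.0018$ to four decimals
(an abstract-style rounding of 0.0013 circulates for the same design; the
methods value $\alpha/k$ is what the package computes). Sensitivity
exclusions drop baseline lipid-medication users and participants with
strictly less than three years of follow-up (exactly 3.0 years is
retained).

Quintile analyses split the observed phenotype, or the genetic
prediction, into equal-frequency fifths and report per-group HRs against
the lowest fifth plus an inverse-variance-weighted trend of log HR on
group median exposure. Numerical conventions: group assignment is by rank
(ties split across boundaries to keep sizes within one of each other —
equivalent to cutting at sample quintiles for tie-free data); duplicated
cut points raise a degenerate-ties error; the reference group enters the
trend at log HR 0 with its infinite nominal weight capped at the largest
finite group weight; the trend slope SE uses the known-variance
weighted-least-squares formula. Subgroup MR refits the full two-stage
pipeline within sex or age strata, skipping strata with fewer than 50
incident events.

## The synthetic cohort generator

`simulateCohort()` emulates the structure of a large prospective biobank
cohort at desk scale, under one global seed:

* **Genotypes** are Binomial(2, EAF) under Hardy–Weinberg; within an LD
  block the latent allele draws share a Gaussian-copula correlation
  `ldRho`, giving tunable dosage correlation with exact marginal HWE.
  Missingness is imposed uniformly at random — on the analysis copy only;
  phenotypes are always generated from the complete matrix.
* **Exposure**: $x = \sum_j \gamma_j g_j + b\,U + \varepsilon$ with
  per-SNP effects drawn with spread (uniform on 0.2–1.8 before scaling;
  the spread keeps the Egger intercept identified) and rescaled so the
  SNPs explain exactly `instrumentR2` of the unit variance; $U$ is a
  standard-normal latent confounder never exposed to analysis code.
  Binary exposures dichotomize the liability at the threshold matching
  the target prevalence.
* **Survival**: exponential event times with hazard
  $h_0\exp(\theta x + c\,U + \sum_j \alpha_j g_j)$ — proportional hazards
  holds exactly. Direct SNP effects $\alpha_j$ are
  $N(\mu_\alpha, \sigma_\alpha)$ on a configurable fraction of SNPs
  (`pleiotropyFraction`), so both directional pleiotropy (nonzero mean)
  and a 30%-invalid instrument set can be generated. Entry is uniform
  over a 5.5-year recruitment window with administrative censoring at
  11.2 years, giving follow-up of mean 8.4 and SD 1.6 years; the default
  baseline hazard (5.3e-4/y) yields a cumulative incidence near 0.4%.
  Prevalent-case flags are drawn with probability increasing in the same
  linear predictor, so the all-case logistic model sees signal.
* **Covariates** (sex, age uniform on 40–69, ten standard-normal PCs,
  chip, and the observational stand-ins) are generated independently of
  exposure and outcome.

What the generator does **not** emulate: realistic human LD maps,
population stratification correlated with exposure, imputation-quality
variation, non-proportional hazards, competing risks, or the joint
distribution of dozens of real phenotypes. Passing simulations therefore
validate the estimators' statistical behaviour under a clean
data-generating process, not robustness to those real-data features.

## Preset evaluation designs and their sizes

`studyScenario()` fixes the simulation designs the package is evaluated
on (driven by `simulationStudy()`; problem sizes are chosen so each study
carries enough events to be informative while a full evaluation runs on a
single CPU in minutes):

* `recovery` / `null` — n = 5,000, 30 independent SNPs, instrument
  $R^2 = 0.05$, confounder paths 0.5/0.5, baseline hazard 0.006/y
  (roughly 400 incident events per replicate); $\theta = \log 1.2$ or 0.
  These measure bias, CI coverage, type-I error, and the confounded
  observational contrast on the same data.
* `egger_null` — n = 1,500 with a ~25% cumulative incidence: the size of
  the intercept test with clean instruments.
* `egger_directional` — directional pleiotropy calibrated to ~30% of the
  per-SNP instrument–outcome signal,
  $\mu_\alpha = \tfrac{3}{7}\theta\bar\gamma$. Because the intercept's
  precision scales as $1/\sqrt{\text{events}}$ and a rare outcome leaves
  it powerless against effects this small, the power design uses a strong
  instrument ($R^2 = 0.30$), n = 40,000 with a common outcome, and no
  latent confounding — a hazard-side confounder acts as unmodelled
  frailty that attenuates all marginal per-SNP log HRs
  (non-collapsibility) and with them the realized intercept. An a priori
  power analysis puts the intercept-test power near 0.75 here.
* `invalid_instruments` — 30% of SNPs carry a large direct effect
  ($\alpha \approx 0.08$), n = 6,000 with a common outcome so the Wald
  ratios are precise enough for the median to discriminate: the
  weighted-median robustness contrast against two-stage/IVW.

A mildly attenuated two-stage mean (a few percent below
$e^\theta = 1.2$) is expected in the confounded recovery design, again
from hazard-ratio non-collapsibility; the acceptance band accommodates
it, and the effect vanishes as the event rate falls toward the
paper-scale incidence.

## Numerical contracts

Cox fits maximize the Efron-corrected partial likelihood (ties in
synthetic continuous time are rare, but Efron is the safer default) by
Newton–Raphson with relative log-likelihood tolerance $10^{-9}$ and at
most 100 iterations; SEs come from the observed information; constant
columns are rejected (the partial likelihood absorbs any constant) and
monotone likelihoods raise errors instead of returning divergent
coefficients. Logistic fits use IRLS with deviance tolerance $10^{-9}$
and raise an explicit error on separation. All 95% intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$, matching standard reporting. The
engine contracts are verified in the test suite against hand-coded
oracles: a grid maximization of the Efron partial likelihood, the 2×2
cross-product odds ratio, the $F = t^2$ Wald identity, and the
generator's stored ground truth.

## Worked example

```{r example}
library(grsMR)
sc <- MrScenario(nSamples = 3000, nSnps = 10, baselineHazard = 0.01,
                 seed = 42)
sim <- simulateCohort(sc)
cohort <- cohortData(sim$panel)
panel <- imputeMissing(sim$panel)
kept <- filterGenomewide(sim$weights)
pruned <- ldPrune(panel, kept, r2Threshold = 0.1)
grs <- computeGrs(panel[pruned, ], kept[kept$snp_id %in% pruned, ])
res <- runMr(cohort, grs, "exposure_sim", panel = panel[pruned, ],
             nBoot = 500, seed = 1)
res$estimates$two_stage_cox
res$estimates$mr_egger
```

## Known limitations

Winner's curse in weight selection is not corrected; the naive two-stage
SE slightly under-covers when instruments weaken; two-sample MR from
summary statistics, multivariable MR, non-linear MR, time-varying
covariates and competing-risks outcomes are out of scope. The
"per unit reflecting one odd" phrasing sometimes attached to per-factor
reporting is interpreted as one reporting unit per factor: 1 SD for
continuous exposures, one category for binary ones.
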