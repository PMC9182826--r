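# assemble aligned pieces for direct MR calls (no prevalent cases)
mrPieces <- function(seed, ...) {
  sim <- quickSim(seed, prevalent = 0, missing = 0, ...)
  co <- sim$cohort
  list(sim = sim, cohort = co, covars = covariateModel(co, "mr"),
       grs = computeGrs(sim$panel, sim$weights))
}

test_that("stage one standardizes the prediction and reports instrument strength", {
  p <- mrPieces(61, n = 4000, m = 20)
  s1 <- stageOne(scores(p$grs), p$cohort$exposure_sim, p$covars)
  expect_lt(abs(mean(s1$prediction)), 1e-10)
  expect_lt(abs(sd(s1$prediction) - 1), 1e-10)
  expect_gt(s1$fStat, 10)
  expect_false(s1$weak)
  expect_identical(s1$scale, "per 1-SD")

  # single-instrument identity F ~ (n-2) R2 / (1 - R2) without covariates
  f0 <- fitLinear(p$cohort$exposure_sim, data.frame(g = scores(p$grs)))
  n <- nrow(p$cohort)
  expect_equal(f0$fStat, (n - 2) * f0$r2 / (1 - f0$r2), tolerance = 1e-8)

  # a null instrument is flagged weak
  set.seed(61)
  expect_warning(
    s0 <- stageOne(rnorm(n), p$cohort$exposure_sim, p$covars),
    "weak instrument")
  expect_lt(s0$partialR2, 0.01)
})

test_that("the per-1-SD hazard ratio is invariant to rescaling the GRS", {
  p <- mrPieces(62, n = 3000, h0 = 0.01)
  r1 <- runMr(p$cohort, p$grs, "exposure_sim", estimators = "two_stage_cox")
  g2 <- new("GrsVector", score = scores(p$grs) * 3.7,
            snps = provenance(p$grs)$snps, log = character(0))
  r2 <- runMr(p$cohort, g2, "exposure_sim", estimators = "two_stage_cox")
  expect_equal(r1$estimates$two_stage_cox@logEstimate,
               r2$estimates$two_stage_cox@logEstimate, tolerance = 1e-8)
})

test_that("with a single SNP the two-stage estimate equals the Wald ratio", {
  p <- mrPieces(63, n = 4000, m = 1, h0 = 0.01, r2 = 0.02)
  co <- p$cohort
  s1 <- stageOne(scores(p$grs), co$exposure_sim, p$covars)
  ts <- stageTwoCox(s1$prediction, co$followup_years, co$event, p$covars,
                    rescale = s1$rescale)
  snp <- perSnpAssociations(p$sim$panel, co$exposure_sim, co$followup_years,
                            co$event, p$covars, minSnps = 1)
  wald <- (snp$beta_out / snp$beta_exp) * sd(co$exposure_sim)
  expect_equal(ts@logEstimate, wald, tolerance = 1e-6)
})

test_that("per-SNP associations recover the generator's exposure effects", {
  p <- mrPieces(64, n = 4000, m = 30, h0 = 0.01)
  co <- p$cohort
  snp <- perSnpAssociations(p$sim$panel, co$exposure_sim, co$followup_years,
                            co$event, p$covars)
  expect_equal(nrow(snp), 30)
  gamma <- p$sim$truth@gamma[snp$snp_id]
  within3 <- abs(snp$beta_exp - gamma) < 3 * snp$se_exp
  expect_gte(sum(within3), 27)
  expect_error(perSnpAssociations(p$sim$panel[1:2, ], co$exposure_sim,
                                  co$followup_years, co$event, p$covars),
               "fewer than 3")
})

test_that("MR-Egger recovers an exact line and ignores SNP orientation", {
  be <- c(0.02, 0.05, 0.08, 0.11, 0.15)
  s <- data.frame(snp_id = paste0("rs", 1:5), beta_exp = be,
                  se_exp = 0.001, beta_out = 0.03 + 0.9 * be, se_out = 0.01)
  e <- mrEgger(s)
  expect_equal(e@logEstimate, 0.9, tolerance = 1e-10)
  expect_equal(e@extras$intercept, 0.03, tolerance = 1e-10)

  s2 <- s
  s2$beta_exp[2] <- -s2$beta_exp[2]  # re-oriented internally
  s2$beta_out[2] <- -s2$beta_out[2]
  e2 <- mrEgger(s2)
  expect_equal(e2@logEstimate, e@logEstimate, tolerance = 1e-12)
  expect_equal(e2@extras$interceptP, e@extras$interceptP, tolerance = 1e-12)

  s3 <- s; s3$beta_exp <- rep(0.1, 5)
  expect_error(mrEgger(s3), "spread")
  expect_error(mrEgger(s[1:2, ]), "at least 3")
})

test_that("the weighted median interpolates correctly and degenerates sanely", {
  s <- data.frame(snp_id = paste0("rs", 1:3),
                  beta_exp = c(1, 1, 1), se_exp = 1e-6,
                  beta_out = c(0.1, 0.2, 0.6), se_out = 1)  # equal weights
  wm <- weightedMedian(s, nBoot = 50, seed = 7)
  expect_equal(wm@logEstimate, 0.2, tolerance = 1e-10)

  # identical ratios: the estimate is that ratio and the bootstrap SE
  # vanishes with the sampling noise
  s2 <- data.frame(snp_id = paste0("rs", 1:4),
                   beta_exp = c(0.5, 1, 1.5, 2), se_exp = 1e-9,
                   beta_out = 0.3 * c(0.5, 1, 1.5, 2), se_out = 1e-9)
  wm2 <- weightedMedian(s2, nBoot = 100, seed = 8)
  expect_equal(wm2@logEstimate, 0.3, tolerance = 1e-6)
  expect_lt(wm2@se, 1e-6)

  s3 <- s; s3$beta_exp <- c(0, 0, 1)
  expect_error(weightedMedian(s3), "at least 3")
})

test_that("IVW reduces to the Wald ratio for one SNP and is exact on a line", {
  s <- data.frame(snp_id = "rs1", beta_exp = 0.08, se_exp = 0.01,
                  beta_out = 0.024, se_out = 0.01)
  expect_error(mrIvw(s), "at least 2")
  s2 <- rbind(s, s)
  s2$snp_id <- c("rs1", "rs2")
  expect_equal(mrIvw(s2)@logEstimate, 0.024 / 0.08, tolerance = 1e-12)
  be <- c(0.02, 0.06, 0.1)
  s3 <- data.frame(snp_id = paste0("rs", 1:3), beta_exp = be, se_exp = 0.01,
                   beta_out = 0.7 * be, se_out = c(0.01, 0.02, 0.03))
  expect_equal(mrIvw(s3)@logEstimate, 0.7, tolerance = 1e-12)
})

test_that("binary exposures are reported per category with an unstandardized prediction", {
  p0 <- quickSim(65, n = 6000, m = 20, h0 = 0.01, prevalent = 0, missing = 0,
                 binaryExposure = TRUE, binaryPrevalence = 0.3)
  grs <- computeGrs(p0$panel, p0$weights)
  res <- runMr(cohortData(p0$panel), grs, "exposure_sim", binary = TRUE,
               estimators = "two_stage_cox")
  expect_identical(res$stageOne$scale, "per category")
  expect_false(isTRUE(all.equal(sd(res$stageOne$prediction), 1)))
  expect_identical(res$estimates$two_stage_cox@scale, "per category")
  expect_true(is.finite(res$estimates$two_stage_cox@logEstimate))
})

test_that("logistic and Cox second stages agree for a rare outcome", {
  p <- mrPieces(66, n = 20000, m = 20, h0 = 0.002)
  res <- runMr(p$cohort, p$grs, "exposure_sim",
               estimators = c("two_stage_cox", "two_stage_logistic"))
  expect_lt(abs(res$estimates$two_stage_cox@logEstimate -
                res$estimates$two_stage_logistic@logEstimate), 0.1)
})

test_that("estimate objects keep their contracts and flatten cleanly", {
  p <- mrPieces(67, n = 2500, m = 8, h0 = 0.01)
  res <- runMr(p$cohort, p$grs, "exposure_sim", panel = p$sim$panel,
               nBoot = 100, seed = 3)
  for (e in res$estimates) {
    expect_s4_class(e, "MrEstimate")
    expect_lte(e@ciLow, estimate(e))
    expect_gte(e@ciHigh, estimate(e))
    expect_identical(e@scale, "per 1-SD")
  }
  tab <- do.call(rbind, lapply(res$estimates, as.data.frame))
  expect_equal(nrow(tab), 5)
  expect_true(all(is.finite(tab$estimate)))
  expect_true(is.finite(tab$egger_intercept_p[tab$estimator == "mr_egger"]))
  # the two-stage and IVW estimators agree within their joint uncertainty
  d <- abs(res$estimates$two_stage_cox@logEstimate -
           res$estimates$ivw@logEstimate)
  expect_lt(d, 3 * (res$estimates$two_stage_cox@se + res$estimates$ivw@se))
})

test_that("subgroup analyses refit per stratum and skip thin strata", {
  p <- mrPieces(68, n = 8000, m = 10, h0 = 0.01)
  sub <- subgroupMr(p$cohort, p$grs, "exposure_sim", by = "sex")
  expect_setequal(names(sub), c("male", "female"))
  lm_ <- sub$male$estimates$two_stage_cox
  lf_ <- sub$female$estimates$two_stage_cox
  # identical causal effect in both sexes by construction
  expect_lt(abs(lm_@logEstimate - lf_@logEstimate),
            3 * (lm_@se + lf_@se))
  none <- subgroupMr(p$cohort, p$grs, "exposure_sim", by = "sex",
                     minEvents = 1e6)
  expect_length(none, 0)
  expect_length(attr(none, "log"), 2)
})

test_that("subgroup estimates diverge when only one sex carries the effect", {
  p <- mrPieces(69, n = 12000, m = 10, h0 = 0.015, theta = log(1.6),
                confExp = 0, confHr = 0)
  co <- p$cohort
  # erase the causal link in males by permuting their outcomes: their
  # survival no longer tracks their exposure (theta effectively 0)
  male <- which(co$sex == 0)
  set.seed(690)
  perm <- sample(male)
  co$followup_years[male] <- co$followup_years[perm]
  co$event[male] <- co$event[perm]
  sub <- subgroupMr(co, p$grs, "exposure_sim", by = "sex")
  est <- vapply(sub, function(s) s$estimates$two_stage_cox@logEstimate, 0)
  expect_gt(est["female"], est["male"])
  expect_gt(est["female"] - est["male"],
            2 * sub$female$estimates$two_stage_cox@se)
})

test_that("without confounding the observational and MR per-SD effects agree", {
  p <- mrPieces(70, n = 8000, m = 20, h0 = 0.01, confExp = 0, confHr = 0)
  co <- p$cohort
  res <- runMr(co, p$grs, "exposure_sim", estimators = "two_stage_cox")
  scan <- runExposureScan(co, exposureSpec("exposure_sim"), k = 1)
  obsPerSd <- log(scan$hr) * sd(co$exposure_sim)
  ts <- res$estimates$two_stage_cox
  obsSe <- (log(scan$ci_high) - log(scan$hr)) / 1.96 * sd(co$exposure_sim)
  expect_lt(abs(ts@logEstimate - obsPerSd), 3 * (ts@se + obsSe))
})
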