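mkWeights <- function(p, beta = rep(0.1, length(p)), ids = NULL) {
  if (is.null(ids)) ids <- paste0("rs", seq_along(p))
  data.frame(snp_id = ids, effect_allele = "A", other_allele = "G",
             beta = beta, se = 0.01, pvalue = p, eaf = 0.3,
             stringsAsFactors = FALSE)
}

test_that("genome-wide filtering keeps strictly sub-threshold p-values", {
  w <- mkWeights(c(1e-9, 1e-7, 4.9e-8))
  kept <- filterGenomewide(w, 5e-8)
  expect_identical(kept$snp_id, c("rs1", "rs3"))
  expect_identical(filterGenomewide(w, 1), w)  # vacuous threshold
  expect_error(filterGenomewide(mkWeights(c(0.5, 5e-8)), 5e-8),
               "no valid instruments")
})

test_that("LD pruning keeps the strongest SNP per correlated pair", {
  set.seed(21)
  n <- 400
  g1 <- rbinom(n, 2, 0.4)
  g2 <- ifelse(runif(n) < 0.97, g1, rbinom(n, 2, 0.4))  # r2 ~ 0.9
  g3 <- rbinom(n, 2, 0.4)
  expect_gt(cor(g1, g2)^2, 0.8)
  panel <- GenotypePanel(rbind(rs1 = g1, rs2 = g2, rs3 = g3))
  w <- mkWeights(c(1e-10, 1e-8, 1e-9))
  kept <- ldPrune(panel, w, 0.1)
  expect_setequal(kept, c("rs1", "rs3"))  # rs2 loses to lower-p rs1
  expect_setequal(ldPrune(panel, w, 1), c("rs1", "rs2", "rs3"))
})

test_that("pruned sets are pairwise independent by brute force", {
  sc <- MrScenario(nSamples = 3000, nSnps = 24, ldBlockSize = 3, ldRho = 0.7,
                   eafRange = c(0.2, 0.8), missingRate = 0, seed = 22)
  set.seed(22)
  panel <- simulateGenotypes(sc)
  w <- mkWeights(runif(24, 1e-12, 1e-8))
  kept <- ldPrune(panel, w, 0.1)
  expect_gt(length(kept), 1)
  cc <- cor(t(dosages(panel)[kept, ]))^2
  expect_lte(max(cc[upper.tri(cc)]), 0.1)
})

test_that("zero-variance SNPs are excluded from pruning with a warning", {
  panel <- GenotypePanel(rbind(rs1 = c(1, 1, 1, 1),
                               rs2 = c(0, 1, 2, 1)))
  expect_warning(kept <- ldPrune(panel, mkWeights(c(1e-10, 1e-9)), 0.1),
                 "zero-variance")
  expect_identical(kept, "rs2")
})

test_that("mean imputation fills exactly the missing cells", {
  d <- rbind(rs1 = c(0, 2, NA), rs2 = c(1, 1, 1))
  out <- dosages(imputeMissing(GenotypePanel(d)))
  expect_identical(unname(out["rs1", ]), c(0, 2, 1))
  expect_identical(unname(out["rs2", ]), c(1, 1, 1))

  d2 <- rbind(rs1 = c(1, 1, NA, NA))
  expect_identical(unname(dosages(imputeMissing(GenotypePanel(d2)))[1, ]),
                   rep(1, 4))
  # identity on complete panels, preserved non-missing means
  p3 <- GenotypePanel(rbind(rs1 = c(0, 1, 2)))
  expect_identical(dosages(imputeMissing(p3)), dosages(p3))
  d4 <- rbind(rs1 = c(0, NA, 2, 1, NA))
  imp <- dosages(imputeMissing(GenotypePanel(d4)))
  expect_equal(mean(imp["rs1", ]), mean(d4["rs1", ], na.rm = TRUE))
  expect_error(imputeMissing(GenotypePanel(rbind(rs1 = c(NA_real_, NA_real_)))),
               "rs1")
})

test_that("allele harmonization flips, drops ambiguous and mismatched SNPs", {
  d <- rbind(rs1 = c(0, 1, 2), rs2 = c(2, 1, 0), rs3 = c(1, 1, 0),
             rs4 = c(0, 0, 1))
  snpInfo <- data.frame(effect_allele = c("A", "G", "A", "A"),
                        other_allele = c("G", "A", "T", "G"))
  panel <- GenotypePanel(d, snpInfo = snpInfo)
  w <- data.frame(snp_id = paste0("rs", 1:4),
                  effect_allele = c("A", "A", "A", "C"),
                  other_allele = c("G", "G", "T", "T"),
                  beta = 0.1, se = 0.01, pvalue = 1e-9, eaf = 0.3)
  expect_warning(expect_warning(h <- harmonizeAlleles(panel, w),
                                "ambiguous"), "mismatch")
  expect_setequal(rownames(h$panel), c("rs1", "rs2"))
  expect_identical(unname(dosages(h$panel)["rs1", ]), c(0, 1, 2))  # matched
  expect_identical(unname(dosages(h$panel)["rs2", ]), c(0, 1, 2))  # 2 - g
  expect_identical(unname(h$log), c(1L, 1L, 1L, 1L))
})

test_that("the weighted GRS matches its defining formula", {
  d <- matrix(c(1, 2), 2, 1, dimnames = list(c("rs1", "rs2"), "s1"))
  w <- mkWeights(c(1e-9, 1e-9), beta = c(0.2, 0.3))
  expect_equal(unname(scores(computeGrs(GenotypePanel(d), w))), 3.2)

  # equal betas cancel: the score is the raw risk-allele count
  set.seed(31)
  d2 <- matrix(rbinom(40, 2, 0.5), 4, 10,
               dimnames = list(paste0("rs", 1:4), paste0("s", 1:10)))
  w2 <- mkWeights(rep(1e-9, 4), beta = rep(0.37, 4))
  expect_equal(unname(scores(computeGrs(GenotypePanel(d2), w2))),
               unname(colSums(d2)))
  # all-zero dosages score zero
  d0 <- matrix(0, 2, 3, dimnames = list(c("rs1", "rs2"), NULL))
  expect_equal(unname(scores(computeGrs(GenotypePanel(d0), w))), rep(0, 3))
})

test_that("the GRS is linear in dosages", {
  set.seed(32)
  m <- 6; n <- 15
  dA <- matrix(rbinom(m * n, 1, 0.5), m, n,
               dimnames = list(paste0("rs", 1:m), NULL))
  dB <- matrix(rbinom(m * n, 1, 0.5), m, n,
               dimnames = list(paste0("rs", 1:m), NULL))
  w <- mkWeights(rep(1e-9, m), beta = runif(m, -0.2, 0.5))
  s <- function(d) unname(scores(computeGrs(GenotypePanel(d), w)))
  expect_equal(s(dA + dB), s(dA) + s(dB), tolerance = 1e-12)
})

test_that("a vanishing signed-beta denominator is an error with an |beta| escape", {
  d <- matrix(c(1, 2), 2, 1, dimnames = list(c("rs1", "rs2"), NULL))
  w <- mkWeights(c(1e-9, 1e-9), beta = c(0.3, -0.3))
  expect_error(computeGrs(GenotypePanel(d), w), "denominator vanishes")
  expect_silent(computeGrs(GenotypePanel(d), w, useAbsoluteWeights = TRUE))
})

test_that("a truth-weighted GRS tracks the generated exposure", {
  sim <- quickSim(33, n = 3000, m = 12, r2 = 0.05)
  panel <- imputeMissing(sim$panel)
  grs <- computeGrs(panel, sim$weights)
  expect_gt(cor(scores(grs), sim$cohort$exposure_sim), 0.1)
  # instruments dropped when absent from the panel, with a warning
  w2 <- rbind(sim$weights,
              within(sim$weights[1, ], {snp_id <- "rs_absent"}))
  expect_warning(g2 <- computeGrs(panel, w2), "absent from panel")
  expect_equal(nrow(provenance(g2)$snps), 12)
})
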