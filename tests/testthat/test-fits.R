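test_that("OLS satisfies its exact and Wald-identity contracts", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 2 * x + 1
  fit <- suppressWarnings(fitLinear(y, data.frame(x = x)))
  expect_equal(fit$r2, 1)
  expect_equal(sum(fit$fit$residuals^2), 0, tolerance = 1e-20)
  expect_equal(fit$coef$estimate[fit$coef$term == "x"], 2)

  set.seed(41)
  x2 <- rnorm(500)
  y2 <- 0.3 * x2 + rnorm(500)
  f2 <- fitLinear(y2, data.frame(x = x2))
  co <- f2$coef[f2$coef$term == "x", ]
  expect_equal(f2$fStat, (co$estimate / co$se)^2)  # F = t^2
  # two-group special case: coefficient is exactly the difference of means
  g <- rep(0:1, each = 20)
  yg <- rnorm(40)
  fg <- fitLinear(yg, data.frame(g = g))
  expect_equal(fg$coef$estimate[fg$coef$term == "g"],
               mean(yg[g == 1]) - mean(yg[g == 0]))
})

test_that("OLS recovers a simulated slope and rejects rank deficiency", {
  set.seed(42)
  x <- rnorm(10000)
  y <- 2 * x + rnorm(10000)
  fit <- fitLinear(y, data.frame(x = x))
  co <- fit$coef[fit$coef$term == "x", ]
  expect_lt(abs(co$estimate - 2), 3 * co$se)
  expect_error(fitLinear(y, data.frame(x = x, x2 = 2 * x)), "collinear")
})

test_that("the Cox Newton fit matches brute-force partial-likelihood maximization", {
  # 8 records, one binary covariate, no ties
  time <- c(1.1, 2.3, 3.7, 4.2, 5.6, 6.1, 7.9, 9.4)
  status <- c(1, 0, 1, 1, 0, 1, 1, 0)
  x <- c(1, 1, 0, 1, 0, 0, 1, 0)
  fit <- fitCox(time, status, data.frame(x = x))
  oracle <- gridMaxCox(time, status, x)
  expect_lt(abs(fit$coef$estimate - oracle), 1e-4)

  # a second configuration, with tied event times exercising Efron weights
  time2 <- c(2, 2, 2, 4, 5, 6, 7, 8, 9, 10)
  status2 <- c(1, 1, 1, 0, 1, 1, 0, 1, 0, 0)
  set.seed(43)
  x2 <- rnorm(10)
  fit2 <- fitCox(time2, status2, data.frame(x = x2))
  expect_lt(abs(fit2$coef$estimate - gridMaxCox(time2, status2, x2)), 1e-4)
})

test_that("Cox estimates recover generated hazard ratios and nulls", {
  set.seed(44)
  n <- 20000
  x <- rnorm(n)
  t0 <- rexp(n) / (0.05 * exp(log(2) * x))
  cens <- runif(n, 1, 10)
  fit <- fitCox(pmin(t0, cens), as.integer(t0 <= cens), data.frame(x = x))
  expect_gt(fit$coef$hr, 1.8)
  expect_lt(fit$coef$hr, 2.2)

  z <- rnorm(n)  # independent of the hazard
  fit0 <- fitCox(pmin(t0, cens), as.integer(t0 <= cens), data.frame(z = z))
  expect_lt(fit0$coef$ciLow, 1)
  expect_gt(fit0$coef$ciHigh, 1)
  expect_equal(fit0$coef$ciLow, exp(fit0$coef$estimate - 1.96 * fit0$coef$se))
})

test_that("Cox contracts reject degenerate inputs", {
  time <- c(1, 2, 3, 4)
  expect_error(fitCox(c(0, 2, 3, 4), c(1, 1, 0, 0), data.frame(x = 1:4)),
               "positive")
  expect_error(fitCox(time, c(0, 0, 0, 0), data.frame(x = 1:4)), "no events")
  expect_error(fitCox(time, c(1, 1, 0, 0), data.frame(x = rep(1, 4))),
               "collinear|rank")
  # monotone likelihood: all events in one arm, the other never at risk late
  tsep <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ssep <- c(1, 1, 1, 1, 0, 0, 0, 0)
  xsep <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(fitCox(tsep, ssep, data.frame(x = xsep)),
               "separate|converge")
})

test_that("Cox coefficients are invariant to monotone time relabelling", {
  set.seed(45)
  n <- 300
  x <- rnorm(n)
  t0 <- rexp(n) / (0.2 * exp(0.5 * x))
  cens <- runif(n, 1, 8)
  time <- pmin(t0, cens); status <- as.integer(t0 <= cens)
  f1 <- fitCox(time, status, data.frame(x = x))
  f2 <- fitCox(time^2, status, data.frame(x = x))  # order-preserving
  expect_equal(f1$coef$estimate, f2$coef$estimate, tolerance = 1e-10)
})

test_that("the proportional-hazards test holds its size under exact PH", {
  set.seed(46)
  rejections <- 0L
  for (i in 1:200) {
    n <- 300
    x <- rnorm(n)
    t0 <- rexp(n) / (0.2 * exp(0.4 * x))
    cens <- runif(n, 0.5, 8)
    fit <- fitCox(pmin(t0, cens), as.integer(t0 <= cens), data.frame(x = x))
    if (phTest(fit)$p[1] < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.12)
})

test_that("the proportional-hazards test detects a time-varying effect", {
  set.seed(47)
  hits <- 0L
  for (i in 1:40) {
    x <- rbinom(400, 1, 0.5)
    d <- simTimeVarying(400, x, h0 = 0.4, b1 = 1.5, b2 = -0.5,
                        tcut = 1, cmax = 6)
    fit <- fitCox(d$time, d$status, data.frame(x = x))
    if (phTest(fit)$p[1] < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 40, 0.5)
})

test_that("the proportional-hazards test requires at least 3 events", {
  fit <- fitCox(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0),
                data.frame(x = c(0.3, -1, 2, 0.5, -0.2)))
  expect_error(phTest(fit), "fewer than 3 events")
})

test_that("logistic regression reproduces the 2x2 cross-product odds ratio", {
  y <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  x <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  fit <- fitLogistic(y, data.frame(x = x))
  co <- fit$coef[fit$coef$term == "x", ]
  expect_equal(co$or, 9, tolerance = 1e-6)  # (30*30)/(10*10)
  expect_equal(co$ciLow, exp(co$estimate - 1.96 * co$se))

  set.seed(48)
  y0 <- rbinom(400, 1, 0.3)
  x0 <- rnorm(400)
  f0 <- fitLogistic(y0, data.frame(x = x0))
  c0 <- f0$coef[f0$coef$term == "x", ]
  expect_lt(c0$ciLow, 1)
  expect_gt(c0$ciHigh, 1)
})

test_that("logistic regression raises errors for separation and one-class data", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)  # complete separation
  expect_error(fitLogistic(y, data.frame(x = x)), "separation")
  expect_error(fitLogistic(rep(1, 6), data.frame(x = x)), "single class")
  expect_error(fitLogistic(c(0, 1, 2, 1, 0, 1), data.frame(x = x)), "0/1")
})

test_that("fits flatten to a uniform results table", {
  set.seed(49)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(x))
  tab <- fitTable(fitLogistic(y, data.frame(x = x)))
  expect_named(tab, c("term", "estimate", "se", "ratio", "ci_low", "ci_high",
                      "p", "n", "events"))
  t0 <- rexp(60); fitc <- fitCox(t0, rep(1L, 60), data.frame(x = x))
  tabc <- fitTable(fitc)
  expect_equal(tabc$ratio, exp(tabc$estimate))
  expect_equal(tabc$events[1], 60)
})
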