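#' @importFrom survival coxph Surv coxph.control cox.zph
NULL

# design must be a data.frame; verifies full rank (with or without an
# implicit intercept) and names the offending columns otherwise
.checkRank <- function(design, addIntercept = TRUE) {
  X <- model.matrix(~., data = design)
  if (!addIntercept) X <- X[, -1, drop = FALSE]
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(X)
}

#' Ordinary least-squares fit with an instrument F-statistic
#'
#' Fits `response ~ design` by OLS with homoskedastic standard errors and
#' reports, for one designated predictor, the single-constraint Wald
#' F-statistic (the squared t-statistic) and the partial R-squared
#' attributable to that predictor given the remaining columns.
#'
#' @param response numeric vector.
#' @param design `data.frame` of predictors (intercept added internally).
#' @param term name of the designated predictor (default: first column).
#' @return list of class `LinearFit`: `coef` table (`estimate`, `se`, `t`,
#'   `p`), `sigma2`, `r2`, `fStat`, `partialR2`, `term`, `n`, and the `lm`
#'   object in `fit`.
#' @export
fitLinear <- function(response, design, term = NULL) {
  design <- as.data.frame(design)
  if (is.null(term)) term <- names(design)[1L]
  stopifnot(term %in% names(design))
  n <- length(response)
  if (n <= ncol(design) + 1L) stop("more parameters than observations")
  .checkRank(design)
  fit <- lm(response ~ ., data = design)
  sm <- summary(fit)
  ct <- sm$coefficients
  if (!term %in% rownames(ct))
    stop("designated term ", term, " not found in the fitted model")
  tStat <- ct[term, "t value"]
  rss1 <- sum(fit$residuals^2)
  others <- setdiff(names(design), term)
  rssNull <- if (length(others))
    sum(lm(response ~ ., data = design[, others, drop = FALSE])$residuals^2)
  else sum((response - mean(response))^2)
  structure(list(
    coef = data.frame(term = rownames(ct), estimate = ct[, 1L], se = ct[, 2L],
                      t = ct[, 3L], p = ct[, 4L], row.names = NULL),
    sigma2 = sm$sigma^2, r2 = sm$r.squared,
    fStat = tStat^2, partialR2 = (rssNull - rss1) / rssNull,
    term = term, n = n, fit = fit), class = "LinearFit")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with the Efron tie correction by
#' Newton-Raphson (relative log-likelihood tolerance 1e-9, at most 100
#' iterations), with standard errors from the observed information. 95%
#' confidence bounds are `exp(coef -/+ 1.96 se)`. No intercept exists in a
#' partial likelihood, so constant design columns are rejected by the rank
#' check, and monotone likelihoods (a covariate separating events) raise an
#' error rather than returning a divergent coefficient.
#'
#' @param followup positive follow-up times.
#' @param event 0/1 event indicator with at least one event.
#' @param design `data.frame` of covariates.
#' @return list of class `CoxFit`: `coef` table (`estimate`, `se`, `hr`,
#'   `ciLow`, `ciHigh`, `p`), `n`, `events`, `loglik`, `iter`, and the
#'   `coxph` object in `fit`.
#' @export
fitCox <- function(followup, event, design) {
  design <- as.data.frame(design)
  if (any(followup <= 0)) stop("follow-up times must be positive")
  event <- as.integer(event)
  if (sum(event) < 1L) stop("no events: the partial likelihood is undefined")
  # the partial likelihood absorbs any constant, so a constant column is as
  # inestimable as one collinear with an intercept: check rank including it
  .checkRank(design, addIntercept = TRUE)
  dat <- cbind(.t = followup, .e = event, design)
  monotone <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.t, .e) ~ ., data = dat, ties = "efron",
          control = coxph.control(eps = 1e-9, iter.max = 100L)),
    warning = function(w) {
      if (grepl("infinite|converged before|out of iterations",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (monotone || !is.null(fit$fail))
    stop("Cox fit did not converge (monotone likelihood or divergence); ",
         "a covariate may perfectly separate events")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  structure(list(
    coef = data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      ciLow = exp(unname(beta) - 1.96 * unname(se)),
                      ciHigh = exp(unname(beta) + 1.96 * unname(se)),
                      p = 2 * pnorm(-abs(unname(beta) / unname(se))),
                      row.names = NULL),
    n = fit$n, events = fit$nevent, loglik = fit$loglik, iter = fit$iter,
    fit = fit), class = "CoxFit")
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Grambsch-Therneau score test of the correlation between scaled
#' Schoenfeld residuals and Kaplan-Meier-transformed event time; returns
#' one p-value per covariate plus a global test.
#'
#' @param coxfit a `CoxFit` from [fitCox()].
#' @return `data.frame` with `term`, `chisq`, `df`, `p`; the last row is
#'   `GLOBAL`.
#' @export
phTest <- function(coxfit) {
  stopifnot(inherits(coxfit, "CoxFit"))
  if (coxfit$events < 3L)
    stop("proportional-hazards test undefined with fewer than 3 events")
  z <- cox.zph(coxfit$fit, transform = "km", global = TRUE)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' Logistic regression fit
#'
#' Newton-Raphson (IRLS) maximum likelihood with relative deviance
#' tolerance 1e-9; 95% bounds `exp(coef -/+ 1.96 se)`. Complete separation
#' is raised as an error instead of silently returning a huge coefficient.
#'
#' @param response 0/1 vector with both classes present.
#' @param design `data.frame` of predictors.
#' @return list of class `LogisticFit`: `coef` table (`estimate`, `se`,
#'   `or`, `ciLow`, `ciHigh`, `p`), `n`, `converged`, and the `glm` object
#'   in `fit`.
#' @export
fitLogistic <- function(response, design) {
  design <- as.data.frame(design)
  response <- as.integer(response)
  if (!all(response %in% c(0L, 1L))) stop("response must be 0/1")
  if (length(unique(response)) < 2L)
    stop("response has a single class; the odds are undefined")
  .checkRank(design)
  dat <- cbind(.y = response, design)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = dat,
        control = list(epsilon = 1e-9, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if ((sep && max(abs(beta[-1L])) > 10) || !fit$converged)
    stop("complete or quasi-complete separation: logistic MLE does not exist")
  se <- sqrt(diag(summary(fit)$cov.scaled))
  structure(list(
    coef = data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), or = exp(unname(beta)),
                      ciLow = exp(unname(beta) - 1.96 * unname(se)),
                      ciHigh = exp(unname(beta) + 1.96 * unname(se)),
                      p = 2 * pnorm(-abs(unname(beta) / unname(se))),
                      row.names = NULL),
    n = length(response), converged = fit$converged, fit = fit),
    class = "LogisticFit")
}

#' Flatten a fit to a results table
#'
#' Serializes a `LinearFit`, `CoxFit` or `LogisticFit` to the flat form
#' `term, estimate, se, ratio, ci_low, ci_high, p, n, events`.
#'
#' @param fit a fit object from [fitLinear()], [fitCox()] or
#'   [fitLogistic()].
#' @return `data.frame`, one row per model term.
#' @export
fitTable <- function(fit) {
  co <- fit$coef
  ratio <- if (!is.null(co$hr)) co$hr else if (!is.null(co$or)) co$or
           else rep(NA_real_, nrow(co))
  ciL <- if (!is.null(co$ciLow)) co$ciLow else rep(NA_real_, nrow(co))
  ciH <- if (!is.null(co$ciHigh)) co$ciHigh else rep(NA_real_, nrow(co))
  data.frame(term = co$term, estimate = co$estimate, se = co$se,
             ratio = ratio, ci_low = ciL, ci_high = ciH, p = co$p,
             n = if (is.null(fit$n)) NA_real_ else fit$n,
             events = if (is.null(fit$events)) NA_real_ else fit$events,
             row.names = NULL)
}
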