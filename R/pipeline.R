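#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) for the run pipeline and
#' returns every problem found at once.
#'
#' @param config list or path to a YAML file. Recognized blocks: exactly
#'   one of `scenario` (simulation parameters for [MrScenario()]) or
#'   `inputs` (paths `weights`, `dosages`, `cohort`); `exposures` (list of
#'   `name`/`unit`/`model`/`binary`); optional `estimators`, `alpha`,
#'   `bonferroni_k`, `grs` (`p_threshold`, `ld_r2`), `n_boot`, `seed`,
#'   `output_dir`.
#' @return list with the normalized `config` and `problems` (character
#'   vector, empty when valid).
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  problems <- character(0)
  hasScenario <- !is.null(config$scenario)
  hasInputs <- !is.null(config$inputs)
  if (hasScenario == hasInputs)
    problems <- c(problems,
                  "exactly one of 'scenario' or 'inputs' must be present")
  if (hasScenario && is.null(config$scenario$seed) && is.null(config$seed))
    problems <- c(problems, "a seed is mandatory when simulating")
  if (hasInputs) {
    for (f in c("weights", "dosages", "cohort"))
      if (is.null(config$inputs[[f]]))
        problems <- c(problems, paste0("inputs$", f, " is missing"))
      else if (!file.exists(config$inputs[[f]]))
        problems <- c(problems, paste0("inputs$", f, ": file not found: ",
                                       config$inputs[[f]]))
  }
  if (is.null(config$exposures) || !length(config$exposures))
    problems <- c(problems, "at least one exposure must be declared")
  else for (e in config$exposures)
    if (is.null(e$name)) problems <- c(problems, "an exposure lacks a name")
  if (!is.null(config$alpha) &&
      (config$alpha <= 0 || config$alpha >= 1))
    problems <- c(problems, "alpha must be in (0,1)")
  config$alpha <- config$alpha %||% 0.05
  config$bonferroni_k <- config$bonferroni_k %||% length(config$exposures)
  config$estimators <- config$estimators %||%
    c("two_stage_cox", "two_stage_logistic", "ivw", "mr_egger",
      "weighted_median")
  config$grs <- config$grs %||% list()
  config$grs$p_threshold <- config$grs$p_threshold %||% 5e-8
  config$grs$ld_r2 <- config$grs$ld_r2 %||% 0.1
  config$n_boot <- config$n_boot %||% 1000L
  config$output_dir <- config$output_dir %||% "grsmr_output"
  list(config = config, problems = problems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate / GRS / observational / MR pipeline
#'
#' Orchestrates the whole analysis from one configuration: simulate a
#' cohort (or read the three delimited inputs), build the weighted GRS
#' (genome-wide filter, allele harmonization where the panel carries allele
#' metadata, LD pruning, mean imputation), run the observational Cox scan
#' with quintile analyses, and run the MR estimator battery per exposure.
#' All outputs are flat TSV tables plus a human-readable run log and a
#' JSON-lines event log; runs are deterministic given the seed.
#'
#' @param config list or YAML path (see [validateConfig()]).
#' @param outDir optional output-directory override.
#' @param seed optional seed override.
#' @param steps which stages to run: any subset of `"grs"`,
#'   `"observational"`, `"mr"` (the MR stage implies the GRS stage; an
#'   empty vector just materializes/validates the inputs).
#' @return Invisibly, a list with the main in-memory results
#'   (`observational`, `mr`, `quintiles`, `grs`, `log`) and `outputs`, the
#'   written file paths.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL,
                        steps = c("grs", "observational", "mr")) {
  stopifnot(all(steps %in% c("grs", "observational", "mr")))
  v <- validateConfig(config)
  if (length(v$problems))
    stop("invalid configuration:\n  - ", paste(v$problems, collapse = "\n  - "))
  config <- v$config
  if (!is.null(outDir)) config$output_dir <- outDir
  if (!is.null(seed)) config$seed <- seed
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  events <- character(0)
  note <- function(msg, ...) {
    msg <- sprintf(msg, ...)
    log <<- c(log, msg)
    events <<- c(events, .jsonLine(event = "log", message = msg))
  }
  note("grsMR %s", as.character(packageVersion("grsMR")))

  if (!is.null(config$scenario)) {
    scArgs <- config$scenario
    scArgs$seed <- scArgs$seed %||% config$seed
    scenario <- do.call(MrScenario, scArgs)
    sim <- simulateCohort(scenario)
    panel <- sim$panel
    weights <- sim$weights
    cohort <- cohortData(panel)
    note("simulated cohort: %d samples, %d SNPs, seed %d",
         ncol(panel), nrow(panel), scenario@seed)
    writeCohortFiles(sim, file.path(config$output_dir, "inputs"))
  } else {
    weights <- readSnpWeights(config$inputs$weights)
    panel <- readDosageMatrix(config$inputs$dosages)
    cohort <- readCohortTable(config$inputs$cohort)
    idx <- match(cohort$sample_id, colnames(panel))
    if (anyNA(idx)) stop("cohort sample ids missing from the dosage matrix")
    panel <- panel[, idx]
    note("read inputs: %d samples, %d SNPs", ncol(panel), nrow(panel))
  }
  set.seed(config$seed %||% 1L)

  # --- GRS construction -----------------------------------------------
  grs <- NULL
  grsTab <- NULL
  analysisPanel <- NULL
  if (any(c("grs", "mr") %in% steps)) {
  kept <- filterGenomewide(weights, config$grs$p_threshold)
  note("genome-wide filter (p < %g): %d of %d SNPs retained",
       config$grs$p_threshold, nrow(kept), nrow(weights))
  rd <- as.data.frame(SummarizedExperiment::rowData(panel))
  if (all(c("effect_allele", "other_allele") %in% names(rd))) {
    h <- harmonizeAlleles(panel, kept)
    panel <- h$panel
    kept <- h$weights
    note("allele harmonization: %d matched, %d flipped, %d ambiguous dropped, %d mismatched dropped",
         h$log["matched"], h$log["flipped"], h$log["ambiguous"],
         h$log["mismatched"])
  } else note("panel carries no allele metadata; weights assumed pre-aligned")
  pruned <- ldPrune(panel, kept, config$grs$ld_r2)
  note("LD pruning (r2 <= %g): %d of %d SNPs retained",
       config$grs$ld_r2, length(pruned), nrow(kept))
  kept <- kept[kept$snp_id %in% pruned, , drop = FALSE]
  analysisPanel <- imputeMissing(panel[pruned, ])
  grs <- computeGrs(analysisPanel, kept)
  grsTab <- data.frame(sample_id = names(scores(grs)), grs = scores(grs))
  note("GRS computed from %d SNPs", nrow(kept))
  }

  # --- exposure registry ----------------------------------------------
  reg <- do.call(rbind, lapply(config$exposures, function(e)
    exposureSpec(e$name, e$unit %||% 1, e$model %||% "observational")))
  binaryFlags <- vapply(config$exposures, function(e) isTRUE(e$binary),
                        logical(1))
  names(binaryFlags) <- reg$name

  # --- observational scan ---------------------------------------------
  scan <- NULL
  quintRows <- list()
  if ("observational" %in% steps) {
  scan <- runExposureScan(cohort, reg, alpha = config$alpha,
                          k = config$bonferroni_k)
  for (m in attr(scan, "log")) note("observational scan: %s", m)
  inc <- cohort[cohort$prevalent == 0L, , drop = FALSE]
  for (nm in reg$name) {
    if (!nm %in% names(inc) || binaryFlags[[nm]]) next
    covars <- covariateModel(inc, reg$model[reg$name == nm])
    okq <- complete.cases(inc[[nm]], covars)
    qr <- tryCatch(
      quintileAnalysis(inc[[nm]][okq], inc$followup_years[okq],
                       inc$event[okq], covars[okq, , drop = FALSE]),
      error = function(e) {
        note("quintiles of %s skipped: %s", nm, conditionMessage(e))
        NULL
      })
    if (!is.null(qr))
      quintRows[[paste0(nm, ".obs")]] <-
        cbind(exposure = nm, source = "observed", qr@groups,
              trend_slope = qr@trendSlope, trend_se = qr@trendSe)
  }

  }

  # --- MR battery ------------------------------------------------------
  mrRows <- list()
  if ("mr" %in% steps) for (nm in reg$name) {
    if (!nm %in% names(cohort)) next
    res <- runMr(cohort, grs, nm, binary = binaryFlags[[nm]],
                 panel = analysisPanel, estimators = config$estimators,
                 nBoot = config$n_boot,
                 seed = (config$seed %||% 1L) + 1L)
    note("MR for %s: first-stage F = %.1f%s", nm, res$stageOne$fStat,
         if (res$stageOne$weak) " (weak-instrument warning)" else "")
    for (est in res$estimates)
      mrRows[[length(mrRows) + 1L]] <- cbind(exposure = nm,
                                             as.data.frame(est))
    sub <- cohort[match(res$sampleIds, cohort$sample_id), , drop = FALSE]
    okp <- sub$prevalent == 0L
    qp <- tryCatch(
      quintilesOfPrediction(res$stageOne$prediction[okp],
                            sub$followup_years[okp], sub$event[okp],
                            covariateModel(sub, "mr")[okp, , drop = FALSE]),
      error = function(e) {
        note("quintiles of predicted %s skipped: %s", nm, conditionMessage(e))
        NULL
      })
    if (!is.null(qp))
      quintRows[[paste0(nm, ".pred")]] <-
        cbind(exposure = nm, source = "predicted", qp@groups,
              trend_slope = qp@trendSlope, trend_se = qp@trendSe)
  }
  mrTab <- .rbindRows(mrRows)
  quintTab <- .rbindRows(quintRows)

  # --- outputs ---------------------------------------------------------
  out <- function(f) file.path(config$output_dir, f)
  if (!is.null(grsTab)) {
    .writeTsv(grsTab, out("grs.tsv"))
    .writeTsv(data.frame(snp_id = provenance(grs)$snps$snp_id,
                         beta = provenance(grs)$snps$beta),
              out("grs_provenance.tsv"))
  }
  if (!is.null(scan)) .writeTsv(scan, out("observational.tsv"))
  if (!is.null(mrTab)) .writeTsv(mrTab, out("mr_estimates.tsv"))
  if (!is.null(quintTab)) .writeTsv(quintTab, out("quintiles.tsv"))
  if (!is.null(mrTab)) {
    forest <- renderForestTable(mrTab, alpha = config$alpha,
                                bonferroni = bonferroniThreshold(
                                  config$alpha, config$bonferroni_k))
    writeLines(forest, out("forest.txt"))
  }
  writeLines(log, out("run.log"))
  writeLines(events, out("events.jsonl"))
  paths <- out(c("grs.tsv", "grs_provenance.tsv", "observational.tsv",
                 "mr_estimates.tsv", "quintiles.tsv", "forest.txt",
                 "run.log", "events.jsonl"))
  invisible(list(observational = scan, mr = mrTab, quintiles = quintTab,
                 grs = grs, log = log,
                 outputs = paths[file.exists(paths)]))
}

# minimal JSON-lines encoder for flat string/number records
.jsonLine <- function(...) {
  kv <- list(...)
  enc <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    v <- if (is.character(v))
      paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", v)), '"')
    else as.character(v)
    paste0('"', k, '":', v)
  }, "")
  paste0("{", paste(enc, collapse = ","), "}")
}

#' Render a forest-style text table of MR estimates
#'
#' One aligned line per exposure x estimator with the ratio estimate and
#' its 95% CI, marked `*` below `alpha` and `**` below the Bonferroni
#' threshold. Every number rendered here also exists in the
#' machine-readable estimates table.
#'
#' @param estimates `data.frame` with `exposure`, `estimator`, `estimate`,
#'   `ci_low`, `ci_high`, `p`.
#' @param alpha raw significance level.
#' @param bonferroni Bonferroni-corrected level.
#' @return character vector of lines.
#' @export
renderForestTable <- function(estimates, alpha = 0.05,
                              bonferroni = alpha / 28) {
  stopifnot(nrow(estimates) >= 1L)
  if (any(!is.finite(estimates$ci_low)) || any(!is.finite(estimates$ci_high)))
    stop("cannot render: empty or non-finite CI fields")
  mark <- ifelse(estimates$p < bonferroni, "**",
                 ifelse(estimates$p < alpha, "*", ""))
  body <- sprintf("%-24s %-20s %6.2f (%.2f–%.2f) %s",
                  estimates$exposure, estimates$estimator,
                  estimates$estimate, estimates$ci_low, estimates$ci_high,
                  mark)
  header <- sprintf("%-24s %-20s %s", "exposure", "estimator",
                    "ratio (95% CI)")
  c(header, body,
    sprintf("*  p < %g   ** p < %g (Bonferroni)", alpha, bonferroni))
}
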