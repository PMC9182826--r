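#' Read a GWAS weight file
#'
#' Tab-delimited with header
#' `snp_id effect_allele other_allele beta se pvalue eaf`.
#'
#' @param path file path.
#' @return `data.frame` of weight records, validated
#'   (`pvalue` in (0,1\], `eaf` in (0,1), `se` > 0, finite `beta`).
#' @export
readSnpWeights <- function(path) {
  w <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
            "pvalue", "eaf")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weight file is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(w$beta))) stop("weight file: beta must be finite")
  if (any(w$se <= 0)) stop("weight file: se must be > 0")
  if (any(w$pvalue <= 0 | w$pvalue > 1)) stop("weight file: pvalue must be in (0,1]")
  if (any(w$eaf <= 0 | w$eaf >= 1)) stop("weight file: eaf must be in (0,1)")
  if (anyDuplicated(w$snp_id)) stop("weight file: duplicated snp_id")
  w[, need]
}

#' Read a dosage matrix file
#'
#' Tab-delimited, first column `sample_id`, one column per SNP, missing
#' encoded `NA`.
#'
#' @param path file path.
#' @return A [GenotypePanel-class] (SNPs x samples).
#' @export
readDosageMatrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (names(d)[1] != "sample_id")
    stop("dosage file must start with a sample_id column")
  ids <- as.character(d$sample_id)
  mat <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(mat) <- ids
  storage.mode(mat) <- "double"
  GenotypePanel(mat)
}

#' Read a cohort table
#'
#' Tab-delimited with a header; must contain `sample_id`, the MR covariates
#' (`sex`, `age`, `pc1`..`pc10`, `chip`), at least one `exposure_*` column,
#' `followup_years`, `event`, `prevalent` and `lipid_med`.
#'
#' @param path file path.
#' @return `data.frame`, one row per participant.
#' @export
readCohortTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age", paste0("pc", 1:10), "chip",
            "followup_years", "event", "prevalent", "lipid_med")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  if (!any(grepl("^exposure_", names(d))))
    stop("cohort file has no exposure_* column")
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Write the three delimited inputs of a simulated cohort
#'
#' Writes `weights.tsv`, `dosages.tsv` and `cohort.tsv` under `dir`,
#' round-trippable by [readSnpWeights()], [readDosageMatrix()] and
#' [readCohortTable()]. Deterministic for a fixed simulation.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
writeCohortFiles <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("weights.tsv", "dosages.tsv", "cohort.tsv"))
  .writeTsv(sim$weights, paths[1])
  d <- t(dosages(sim$panel))  # samples x SNPs
  dosageTab <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .writeTsv(dosageTab, paths[2])
  cohort <- cohortData(sim$panel)
  .writeTsv(cohort, paths[3])
  invisible(paths)
}

.writeTsv <- function(df, path) {
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
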