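# shared helpers: covariate adjustment sets and quintile grouping

#' Build a covariate adjustment set from a cohort table
#'
#' `"mr"` is the instrumental-variable adjustment set: sex, age, the first
#' ten genetic principal components, and genotyping chip.
#' `"observational"` is the epidemiological set: sex, age in 5-year bands,
#' family history, education and income categories, Townsend deprivation,
#' METs, alcohol, smoking status and systolic blood pressure;
#' `"observational_lipid"` additionally adjusts for cholesterol-lowering
#' medication (used for lipid exposures).
#'
#' @param cohort cohort `data.frame`.
#' @param model adjustment-set id.
#' @return `data.frame` of covariates (factors where categorical).
#' @export
covariateModel <- function(cohort,
                           model = c("mr", "observational",
                                     "observational_lipid")) {
  model <- match.arg(model)
  if (model == "mr") {
    cols <- c("sex", "age", paste0("pc", 1:10), "chip")
    miss <- setdiff(cols, names(cohort))
    if (length(miss)) stop("cohort lacks MR covariates: ",
                           paste(miss, collapse = ", "))
    return(cohort[, cols, drop = FALSE])
  }
  cols <- c("sex", "age", "family_history", "education", "income",
            "townsend", "mets", "alcohol", "smoking_status", "sbp")
  if (model == "observational_lipid") cols <- c(cols, "lipid_med")
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("cohort lacks observational covariates: ",
                         paste(miss, collapse = ", "))
  out <- cohort[, cols, drop = FALSE]
  # age enters in 5-year bands as ordered category indicators
  out$age <- factor(.ageBand(cohort$age))
  out$education <- factor(out$education)
  out$income <- factor(out$income)
  out$smoking_status <- factor(out$smoking_status)
  names(out)[names(out) == "age"] <- "age_band"
  out
}

.ageBand <- function(age) {
  lo <- pmin(pmax(5 * floor(age / 5), 35), 70)
  sprintf("%d-%d", lo, lo + 4)
}

# equal-frequency fifths by rank; for tie-free data this is identical to
# cutting at the sample quintiles with values equal to a cut point going to
# the lower group, and under moderate ties it keeps group sizes within one
# (tied values may straddle a boundary). Heavy ties (duplicated cut points)
# are an error.
.quintileGroups <- function(x, what = "exposure") {
  if (length(unique(x)) < 5L)
    stop("quintile analysis needs >= 5 distinct values of ", what)
  cuts <- unname(quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7))
  if (anyDuplicated(cuts))
    stop("heavy ties make quintiles degenerate for ", what)
  group <- as.integer(ceiling(5L * rank(x, ties.method = "first") /
                                length(x)))
  list(group = group, cuts = cuts)
}

# rbind a list of data.frame rows, NULL when empty (bare
# do.call(rbind, ...) on an empty list would swallow its options argument)
.rbindRows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
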