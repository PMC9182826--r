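#' Filter weights to genome-wide significance
#'
#' Keeps instrument records with GWAS `pvalue` strictly below the threshold
#' (conventionally 5e-8), preserving order.
#'
#' @param weights weight `data.frame` (see [readSnpWeights()]).
#' @param threshold significance threshold in (0,1).
#' @return The retained rows.
#' @export
filterGenomewide <- function(weights, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1 || threshold == 1)
  kept <- weights[weights$pvalue < threshold, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("no valid instruments: every p-value is at or above ", threshold)
  kept
}

#' Greedy LD pruning by squared dosage correlation
#'
#' Visits SNPs in ascending GWAS p-value (strongest signal first) and
#' retains a SNP iff its squared sample dosage correlation with every
#' already-retained SNP is at or below `r2Threshold`. Zero-variance SNPs
#' cannot be assessed and are excluded with a warning. Missing dosages are
#' handled by pairwise-complete correlations.
#'
#' @param panel a [GenotypePanel-class].
#' @param weights weight `data.frame` restricted to SNPs present in the
#'   panel (rows absent from the panel are ignored with a warning).
#' @param r2Threshold maximum pairwise r^2 among retained SNPs.
#' @return Character vector of retained SNP ids.
#' @export
ldPrune <- function(panel, weights, r2Threshold = 0.1) {
  stopifnot(r2Threshold >= 0, r2Threshold <= 1)
  inPanel <- weights$snp_id %in% rownames(panel)
  if (!all(inPanel)) {
    warning(sum(!inPanel), " weight SNP(s) absent from panel, ignored")
    weights <- weights[inPanel, , drop = FALSE]
  }
  if (nrow(weights) == 0L) stop("no weight SNPs present in the panel")
  ord <- weights$snp_id[order(weights$pvalue)]
  d <- dosages(panel)[ord, , drop = FALSE]
  v <- apply(d, 1L, var, na.rm = TRUE)
  if (any(zero <- !is.finite(v) | v == 0)) {
    warning("zero-variance SNP(s) excluded from pruning: ",
            paste(ord[zero], collapse = ", "))
    ord <- ord[!zero]
    d <- d[!zero, , drop = FALSE]
  }
  kept <- character(0)
  for (id in ord) {
    if (length(kept)) {
      r <- suppressWarnings(
        cor(d[id, ], t(d[kept, , drop = FALSE]), use = "pairwise.complete.obs"))
      if (any(r^2 > r2Threshold, na.rm = TRUE)) next
    }
    kept <- c(kept, id)
  }
  kept
}

#' Mean-impute missing dosages
#'
#' Replaces each missing cell by the SNP's mean over its non-missing
#' samples, leaving observed values untouched.
#'
#' @param panel a [GenotypePanel-class].
#' @return The completed panel.
#' @export
imputeMissing <- function(panel) {
  d <- dosages(panel)
  nMissing <- rowSums(is.na(d))
  if (any(full <- nMissing == ncol(d)))
    stop("SNP(s) with no observed dosage cannot be mean-imputed: ",
         paste(rownames(d)[full], collapse = ", "))
  if (any(nMissing > 0L)) {
    means <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- means[idx[, 1L]]
    SummarizedExperiment::assay(panel, "dosage") <- d
  }
  panel
}

#' Harmonize panel alleles with the weight file
#'
#' Aligns the dosage matrix to the weight file's effect alleles. Where the
#' panel's counted allele equals the weight record's `other_allele`, the
#' dosage `g` becomes `2 - g`. Strand-ambiguous SNPs (A/T or C/G pairs) and
#' unresolvable allele mismatches are dropped with a warning.
#'
#' @param panel a [GenotypePanel-class] whose `rowData` has
#'   `effect_allele` and `other_allele` (the panel's counted allele pair).
#' @param weights weight `data.frame`.
#' @return list with the aligned `panel`, the matching `weights`, and
#'   `log` counts (`matched`, `flipped`, `ambiguous`, `mismatched`).
#' @export
harmonizeAlleles <- function(panel, weights) {
  rd <- as.data.frame(SummarizedExperiment::rowData(panel))
  if (!all(c("effect_allele", "other_allele") %in% names(rd)))
    stop("panel rowData must carry effect_allele and other_allele")
  common <- intersect(weights$snp_id, rownames(panel))
  weights <- weights[match(common, weights$snp_id), , drop = FALSE]
  rd <- rd[common, , drop = FALSE]
  amb <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
                        (a == "C" & b == "G") | (a == "G" & b == "C")
  ambiguous <- amb(weights$effect_allele, weights$other_allele)
  match_ <- rd$effect_allele == weights$effect_allele &
            rd$other_allele == weights$other_allele
  flip <- rd$effect_allele == weights$other_allele &
          rd$other_allele == weights$effect_allele
  keep <- !ambiguous & (match_ | flip)
  if (any(ambiguous))
    warning(sum(ambiguous), " strand-ambiguous SNP(s) dropped")
  if (any(!ambiguous & !match_ & !flip))
    warning(sum(!ambiguous & !match_ & !flip), " allele-mismatched SNP(s) dropped")
  panel <- panel[common[keep], ]
  weights <- weights[keep, , drop = FALSE]
  doFlip <- flip[keep]
  if (any(doFlip)) {
    d <- dosages(panel)
    d[doFlip, ] <- 2 - d[doFlip, ]
    SummarizedExperiment::assay(panel, "dosage") <- d
    rdk <- SummarizedExperiment::rowData(panel)
    tmp <- rdk$effect_allele[doFlip]
    rdk$effect_allele[doFlip] <- rdk$other_allele[doFlip]
    rdk$other_allele[doFlip] <- tmp
    SummarizedExperiment::rowData(panel) <- rdk
  }
  list(panel = panel, weights = weights,
       log = c(matched = sum(match_ & keep), flipped = sum(doFlip),
               ambiguous = sum(ambiguous),
               mismatched = sum(!ambiguous & !match_ & !flip)))
}

#' Compute the weighted genetic risk score
#'
#' For retained SNPs `1..n` with GWAS effect sizes `beta_j` and per-sample
#' dosages `g_j`, the score is
#' `(beta_1 g_1 + ... + beta_n g_n) / ((beta_1 + ... + beta_n) / n)`,
#' i.e. the beta-weighted allele count normalized by the mean effect size,
#' so an equal-beta score reduces to the raw risk-allele count.
#'
#' @param panel a complete [GenotypePanel-class] (run [imputeMissing()]
#'   first).
#' @param weights weight `data.frame`; SNPs absent from the panel are
#'   dropped from the formula (`n` decreases) with a warning.
#' @param useAbsoluteWeights use `|beta|` in the normalizing denominator
#'   (common practice when betas have mixed signs); the default is the
#'   signed sum exactly as in the defining formula.
#' @return A [GrsVector-class].
#' @examples
#' d <- matrix(c(1, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' w <- data.frame(snp_id = c("a", "b"), beta = c(0.2, 0.3))
#' scores(computeGrs(GenotypePanel(d), w))  # 3.2
#' @export
computeGrs <- function(panel, weights, useAbsoluteWeights = FALSE) {
  if (nrow(weights) == 0L) stop("no instruments supplied")
  logMsg <- character(0)
  inPanel <- weights$snp_id %in% rownames(panel)
  if (!all(inPanel)) {
    logMsg <- c(logMsg, paste(sum(!inPanel), "weight SNP(s) absent from panel, dropped"))
    warning(logMsg[length(logMsg)])
    weights <- weights[inPanel, , drop = FALSE]
    if (nrow(weights) == 0L) stop("no weight SNPs present in the panel")
  }
  d <- dosages(panel)[weights$snp_id, , drop = FALSE]
  if (anyNA(d)) stop("panel has missing dosages; run imputeMissing() first")
  beta <- weights$beta
  denomBeta <- if (useAbsoluteWeights) abs(beta) else beta
  denom <- sum(denomBeta) / length(beta)
  if (abs(denom) < 1e-12)
    stop("mean effect size is zero: the normalizing denominator vanishes ",
         "(mixed-sign betas; consider useAbsoluteWeights = TRUE)")
  score <- as.numeric(crossprod(d, beta)) / denom
  new("GrsVector", score = setNames(score, colnames(d)),
      snps = data.frame(snp_id = weights$snp_id, beta = beta,
                        stringsAsFactors = FALSE),
      log = c(logMsg,
              sprintf("%d SNPs in score; denominator %.6g (%s betas)",
                      length(beta), denom,
                      if (useAbsoluteWeights) "absolute" else "signed")))
}
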