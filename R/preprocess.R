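#' Close a count table to relative abundances
#'
#' Divides each sample (row) of a count block by its total so rows sum to 1.
#'
#' @param block An [omics_block()] of kind `"counts"`.
#' @return An [omics_block()] of kind `"intensity"` holding per-sample
#'   relative abundances.
#' @export
relative_abundance <- function(block) {
  if (!is_omics_block(block)) block <- omics_block(block, kind = "counts")
  if (block$kind != "counts") abort("`relative_abundance()` expects a counts block.")
  totals <- rowSums(block$values)
  if (any(totals == 0)) {
    bad <- block$sample_ids[totals == 0]
    abort(sprintf(
      "Sample(s) with zero total counts cannot be closed: %s",
      paste(bad, collapse = ", ")
    ))
  }
  replace_values(block, block$values / totals, kind = "intensity")
}

#' Filter features by relative abundance and prevalence
#'
#' Keeps a feature when its per-sample relative abundance exceeds
#' `abundance_threshold` in at least a fraction `prevalence_threshold` of the
#' samples. Count blocks are closed internally before the rule is applied; the
#' returned block keeps the original (unclosed) values. The defaults mirror
#' the published rule (> 20\% abundance in >= 20\% of samples), which is
#' unusually stringent for real tables — both thresholds are tunable.
#'
#' @param block An [omics_block()] (counts or relative abundances).
#' @param abundance_threshold Relative-abundance cutoff in `[0, 1]` (strict
#'   `>` comparison).
#' @param prevalence_threshold Minimum fraction of samples in `[0, 1]`
#'   (`>=` comparison).
#' @return The filtered [omics_block()]; feature order preserved. An empty
#'   result is returned with a warning, not an error.
#' @export
filter_features <- function(block, abundance_threshold = 0.2,
                            prevalence_threshold = 0.2) {
  if (!is_omics_block(block)) abort("`block` must be an omics_block.")
  if (abundance_threshold < 0 || abundance_threshold > 1 ||
      prevalence_threshold < 0 || prevalence_threshold > 1) {
    abort("Thresholds must lie in [0, 1].")
  }
  rel <- if (block$kind == "counts") relative_abundance(block)$values else block$values
  prevalence <- colMeans(rel > abundance_threshold)
  keep <- prevalence >= prevalence_threshold
  if (!any(keep)) {
    warn("No feature passed the abundance/prevalence filter; returning an empty block.")
  }
  replace_values(block, block$values[, keep, drop = FALSE])
}

#' Log10-transform a block
#'
#' Multivariate stages of the pipeline operate on log10-transformed data.
#'
#' @param block An [omics_block()].
#' @param pseudocount Nonnegative offset added before taking logs (needed for
#'   tables with zeros).
#' @return An [omics_block()] of kind `"intensity"`.
#' @export
log10_transform <- function(block, pseudocount = 0) {
  if (!is_omics_block(block)) abort("`block` must be an omics_block.")
  if (pseudocount < 0) abort("`pseudocount` must be nonnegative.")
  shifted <- block$values + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    bad <- head(bad, 5)
    abort(sprintf(
      "log10 undefined for nonpositive values; e.g. %s",
      paste(sprintf(
        "[%s, %s]", rownames(block$values)[bad[, 1]],
        colnames(block$values)[bad[, 2]]
      ), collapse = ", ")
    ))
  }
  replace_values(block, log10(shifted), kind = "intensity")
}

#' Standardize features as z-scores across samples
#'
#' Each feature is centered and scaled to unit variance (denominator `n - 1`)
#' across samples, the standardization used before hierarchical clustering.
#' Constant features are dropped with a warning.
#'
#' @param block An [omics_block()].
#' @return An [omics_block()] of kind `"intensity"` with per-feature mean 0
#'   and sd 1.
#' @export
zscore <- function(block) {
  if (!is_omics_block(block)) abort("`block` must be an omics_block.")
  s <- col_sds(block$values)
  if (any(s == 0)) {
    warn(sprintf("Dropping %d constant feature(s) before z-scoring.", sum(s == 0)))
  }
  keep <- s > 0
  v <- block$values[, keep, drop = FALSE]
  v <- sweep(sweep(v, 2, colMeans(v), "-"), 2, s[keep], "/")
  replace_values(block, v, kind = "intensity")
}

#' Assign samples to response quartiles
#'
#' Cut points are the 25th/50th/75th empirical percentiles (type-7 linear
#' interpolation); a value equal to a cut point goes to the lower quartile.
#'
#' @param values Numeric vector, length >= 4.
#' @return Ordered factor with levels `Q1 < Q2 < Q3 < Q4`.
#' @export
#' @examples
#' table(assign_quartiles(1:8))
assign_quartiles <- function(values) {
  if (length(values) < 4) abort("Quartile assignment needs at least 4 values.")
  check_no_na(values, "values")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (length(unique(values)) == 1L) {
    warn("All values identical; every sample assigned to Q1.")
    return(factor(rep("Q1", length(values)),
      levels = c("Q1", "Q2", "Q3", "Q4"), ordered = TRUE
    ))
  }
  idx <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  factor(paste0("Q", idx), levels = c("Q1", "Q2", "Q3", "Q4"), ordered = TRUE)
}
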