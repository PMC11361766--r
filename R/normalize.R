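#' Counts-per-million normalization
#'
#' Scales each sample (column) so it sums to one million, the within-library
#' relative abundance used throughout MeRIP enrichment and the decay
#' calibration.
#'
#' @param m A [count_matrix()] or a numeric matrix with sample columns.
#' @return A real matrix of the same shape; every column sums to 1e6.
#' @export
cpm_normalize <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  tot <- colSums(counts)
  zero <- which(tot <= 0)
  if (length(zero) > 0) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Remove weakly expressed features
#'
#' Keeps features with at least `min_count` reads in at least `min_samples`
#' samples, the standard pre-filter applied before differential testing.
#'
#' @param m A [count_matrix()].
#' @param min_count Minimum read count per qualifying sample (default 10).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return The filtered `count_matrix`; feature order preserved. An empty
#'   result is allowed.
#' @export
filter_low_expression <- function(m, min_count = 10, min_samples = 3) {
  stopifnot(inherits(m, "count_matrix"), min_count >= 0)
  if (min_samples > ncol(m$counts)) {
    stop("min_samples exceeds the number of samples")
  }
  keep <- rowSums(m$counts >= min_count) >= min_samples
  m[keep, ]
}

#' Median-of-ratios size factors
#'
#' Per-sample depth factors computed as the median ratio of each sample's
#' counts to the geometric-mean reference across samples, using only
#' features observed in every sample. Dividing a sample's counts by its
#' factor puts all samples on a common scale; a pure depth difference of
#' 2x yields factors in ratio 1:2.
#'
#' @param m A [count_matrix()] or numeric count matrix.
#' @return Named positive numeric vector, one factor per sample, scaled to
#'   geometric mean 1.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop("no feature has nonzero counts in every sample; ",
         "use CPM normalization instead")
  }
  lc <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(lc)
  f <- apply(lc - ref, 2, stats::median)
  f <- exp(f - mean(f))
  stats::setNames(f, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; adjusted values are monotone in
#' the raw p-values and never smaller than them.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
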