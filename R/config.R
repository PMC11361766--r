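#' Analysis configuration
#'
#' Central container for the thresholds shared across the pipeline: the
#' FDR cut-off for differential methylation calls, the adjusted-p cut-off
#' for reader-target calls, the expression pre-filter, the pseudocount
#' applied wherever a log-ratio is formed, and the decay time-course
#' design.
#'
#' All threshold comparisons are strict (`<`), matching the calling rules
#' the defaults encode (methylation FDR < 0.01, target p-adjusted < 0.05,
#' at least 10 reads in at least 3 samples).
#'
#' @param fdr_methylation FDR threshold for hypo/hyper classification
#'   (default 0.01).
#' @param padj_targets Adjusted-p threshold for RIP target calling
#'   (default 0.05).
#' @param min_count,min_samples Expression filter: keep features with
#'   `>= min_count` reads in `>= min_samples` samples (defaults 10, 3).
#' @param pseudocount Haldane-Anscombe style pseudocount for log-ratios
#'   (default 0.5).
#' @param seed Integer seed feeding every stochastic operation.
#' @param timepoints_h Decay time-course sampling times in hours, sorted,
#'   starting at 0 (default `c(0, 3, 6)`).
#' @param halflife_average One of `"rate"` (average the per-timepoint decay
#'   constants, then take ln2/K; default) or `"halflife"` (average the
#'   per-timepoint half-lives).
#' @param calibration_scale `"loglog"` (default) or `"linear"` spike-in
#'   calibration regression.
#' @param nonhypo_includes_hyper Keep hypermethylated genes in the
#'   "non-hypo" comparison group (default TRUE).
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(fdr_methylation = 0.01,
                            padj_targets = 0.05,
                            min_count = 10,
                            min_samples = 3,
                            pseudocount = 0.5,
                            seed = 1L,
                            timepoints_h = c(0, 3, 6),
                            halflife_average = c("rate", "halflife"),
                            calibration_scale = c("loglog", "linear"),
                            nonhypo_includes_hyper = TRUE) {
  halflife_average <- match.arg(halflife_average)
  calibration_scale <- match.arg(calibration_scale)
  stopifnot(
    fdr_methylation > 0, fdr_methylation < 1,
    padj_targets > 0, padj_targets < 1,
    min_count >= 0, min_samples >= 1,
    pseudocount > 0,
    length(timepoints_h) >= 2,
    timepoints_h[1] == 0,
    !is.unsorted(timepoints_h, strictly = TRUE)
  )
  structure(list(
    fdr_methylation = fdr_methylation,
    padj_targets = padj_targets,
    min_count = as.integer(min_count),
    min_samples = as.integer(min_samples),
    pseudocount = pseudocount,
    seed = as.integer(seed),
    timepoints_h = as.numeric(timepoints_h),
    halflife_average = halflife_average,
    calibration_scale = calibration_scale,
    nonhypo_includes_hyper = nonhypo_includes_hyper
  ), class = "analysis_config")
}
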