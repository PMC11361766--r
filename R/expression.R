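# shared two-group differential core: filter, size factors, log2 + pseudocount,
# Welch t per feature. `groups` is a character vector over samples with
# exactly the two levels (a, b); delta is b minus a.
.de_core <- function(m, groups, level_a, level_b, config) {
  sel_a <- groups == level_a
  sel_b <- groups == level_b
  if (sum(sel_a) < 2 || sum(sel_b) < 2) {
    stop("need at least 2 replicates per group after filtering")
  }
  mf <- filter_low_expression(m, config$min_count, config$min_samples)
  if (nrow(mf$counts) == 0) stop("no features pass the expression filter")
  sf <- size_factors(mf)
  norm <- sweep(mf$counts, 2, sf, "/")
  lg <- log2(norm + config$pseudocount)
  wt <- .welch_t_rows(lg[, sel_a, drop = FALSE], lg[, sel_b, drop = FALSE])
  data.frame(
    gene_id = rownames(mf$counts),
    log2fc = wt$diff,
    p = wt$p,
    padj = bh_adjust(wt$p),
    mean_norm_a = rowMeans(norm[, sel_a, drop = FALSE]),
    mean_norm_b = rowMeans(norm[, sel_b, drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' Differential expression between two conditions
#'
#' Filters weakly expressed genes, normalizes depth with median-of-ratios
#' size factors, and tests each gene with a two-sided Welch t-test on
#' log2(normalized count + pseudocount) across replicates; p-values are BH
#' adjusted. The log2 fold change is the difference of group means on the
#' same scale, so it is invariant to rescaling any sample's depth.
#'
#' @param m A [count_matrix()] containing both conditions.
#' @param cond_a,cond_b Condition labels; `log2fc` is `cond_b` vs `cond_a`.
#' @param config An [analysis_config()] (filter, pseudocount).
#' @return Data frame of class `"diff_expr"`: `gene_id`, `log2fc`, `p`,
#'   `padj`, `mean_norm_<cond_a>`, `mean_norm_<cond_b>`.
#' @export
differential_expression <- function(m, cond_a = "control", cond_b = "patient",
                                    config = analysis_config()) {
  stopifnot(inherits(m, "count_matrix"))
  use <- m$samples$condition %in% c(cond_a, cond_b)
  m2 <- m[, use]
  out <- .de_core(m2, m2$samples$condition, cond_a, cond_b, config)
  names(out)[names(out) == "mean_norm_a"] <- paste0("mean_norm_", cond_a)
  names(out)[names(out) == "mean_norm_b"] <- paste0("mean_norm_", cond_b)
  class(out) <- c("diff_expr", "data.frame")
  attr(out, "conditions") <- c(cond_a, cond_b)
  out
}

#' Expression-shift test between hypo and non-hypo gene groups
#'
#' Two-sided Wilcoxon rank-sum test on per-gene log2 fold changes, hypo
#' genes versus all other detected genes, with empirical CDF coordinates
#' for both groups (the cumulative-distribution representation of the
#' shift).
#'
#' @param de A `"diff_expr"` data frame.
#' @param hypo_set Character vector of hypomethylated gene ids.
#' @return List of class `"shift_result"` with group sizes, medians,
#'   `delta_median` (hypo minus non-hypo), `statistic`, `p_value` and an
#'   `ecdf` data frame (`group`, `x`, `F`).
#' @export
group_shift_test <- function(de, hypo_set) {
  in_hypo <- de$gene_id %in% hypo_set
  x_hypo <- de$log2fc[in_hypo]
  x_rest <- de$log2fc[!in_hypo]
  if (length(x_hypo) == 0 || length(x_rest) == 0) {
    stop("both groups must be nonempty after intersection with detected genes")
  }
  wt <- wilcoxon_ranksum(x_hypo, x_rest)
  ecdf_tab <- function(v, lab) {
    v <- sort(v)
    data.frame(group = lab, x = v, F = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }
  structure(list(
    labels = c("hypo", "nonhypo"),
    n = c(length(x_hypo), length(x_rest)),
    n_censored = c(0L, 0L),
    median_a = stats::median(x_hypo),
    median_b = stats::median(x_rest),
    delta_median = stats::median(x_hypo) - stats::median(x_rest),
    median_ratio = NA_real_,
    statistic = wt$statistic,
    p_value = wt$p_value,
    ecdf = rbind(ecdf_tab(x_hypo, "hypo"), ecdf_tab(x_rest, "nonhypo"))
  ), class = "shift_result")
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification against an internal-control transcript
#' and a calibrator sample:
#' `dCt = Ct_target - Ct_reference` per sample,
#' `fold = 2^-(dCt_test - dCt_calibrator)`.
#'
#' @param ct_target_test,ct_reference_test Ct values in the test sample.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator sample.
#' @return Positive fold change (vectorized).
#' @export
rtqpcr_relative_expression <- function(ct_target_test, ct_reference_test,
                                       ct_target_calibrator,
                                       ct_reference_calibrator) {
  stopifnot(all(is.finite(c(ct_target_test, ct_reference_test,
                            ct_target_calibrator, ct_reference_calibrator))))
  dct_test <- ct_target_test - ct_reference_test
  dct_cal <- ct_target_calibrator - ct_reference_calibrator
  2^-(dct_test - dct_cal)
}
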