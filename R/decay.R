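#' Per-sample spike-in calibration
#'
#' Fits, for every sample, the conversion from within-library CPM to
#' absolute amount: ordinary least squares of log10(amount_attomole) on
#' log10(CPM) over the spike-ins detected in that sample (default), or on
#' the linear scale. Because a fixed proportion of the spike-in mix goes
#' into every sample, this calibration is what carries absolute units
#' through a transcription-shutoff time course in which total RNA mass is
#' falling.
#'
#' @param m A [count_matrix()] whose `feature_kind` marks spike-in rows.
#' @param ref Spike-in reference data frame (`spike_id`,
#'   `amount_attomole`), e.g. from [spikein_reference()] or
#'   [read_spikein_reference()].
#' @param scale `"loglog"` (default) or `"linear"`.
#' @return Data frame of class `"calibration_fits"`: `sample_id`, `slope`,
#'   `intercept`, `r_squared`, `n_spikes_used`, plus a `scale` attribute.
#' @export
fit_spikein_calibration <- function(m, ref, scale = c("loglog", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(m, "count_matrix"))
  spikes <- rownames(m$counts)[m$feature_kind == "spikein"]
  spikes <- intersect(spikes, ref$spike_id)
  if (length(spikes) < 3) stop("need at least 3 spike-in features in the matrix")
  cpm <- cpm_normalize(m)
  amount <- ref$amount_attomole[match(spikes, ref$spike_id)]
  fits <- lapply(colnames(cpm), function(sid) {
    x <- cpm[spikes, sid]
    use <- x > 0
    if (sum(use) < 3) {
      stop(sprintf("sample '%s' has fewer than 3 detected spike-ins", sid))
    }
    if (scale == "loglog") {
      xv <- log10(x[use]); yv <- log10(amount[use])
    } else {
      xv <- x[use]; yv <- amount[use]
    }
    slope <- stats::cov(xv, yv) / stats::var(xv)
    intercept <- mean(yv) - slope * mean(xv)
    ssr <- sum((yv - (intercept + slope * xv))^2)
    sst <- sum((yv - mean(yv))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 0
    data.frame(sample_id = sid, slope = slope, intercept = intercept,
               r_squared = r2, n_spikes_used = sum(use),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  class(out) <- c("calibration_fits", "data.frame")
  attr(out, "scale") <- scale
  out
}

#' Convert CPM to attomole through a calibration fit
#'
#' Applies one sample's calibration: `10^(slope * log10(cpm) + intercept)`
#' on the log-log scale, or `slope * cpm + intercept` on the linear scale.
#' Non-positive CPM (feature undetected) returns `NA` -- a censored value,
#' not zero.
#'
#' @param cpm Numeric vector of CPM values.
#' @param fit One row of a `"calibration_fits"` data frame (or any list
#'   with `slope` and `intercept`).
#' @param scale `"loglog"` (default) or `"linear"`.
#' @return Attomole estimates, `NA` where `cpm <= 0`.
#' @export
cpm_to_attomole <- function(cpm, fit, scale = c("loglog", "linear")) {
  scale <- match.arg(scale)
  out <- rep(NA_real_, length(cpm))
  ok <- is.finite(cpm) & cpm > 0
  if (scale == "loglog") {
    out[ok] <- 10^(fit$slope * log10(cpm[ok]) + fit$intercept)
  } else {
    out[ok] <- fit$slope * cpm[ok] + fit$intercept
  }
  out
}

#' First-order decay rate from a time course
#'
#' Under transcription shutoff, `ln(C_t / C0) = -K t`. Each timepoint
#' `t > 0` with positive abundance yields `K_t = -ln(C_t / C0) / t`; the
#' returned rate is the arithmetic mean of the `K_t`, which is exact for a
#' noiseless exponential (every timepoint agrees) and uses all timepoints
#' otherwise.
#'
#' @param abundances Abundances `C(t)` matching `timepoints_h`; the t = 0
#'   entry defines `C0`.
#' @param timepoints_h Sampling times in hours; must include 0.
#' @return The decay rate in 1/h (can be negative for apparently
#'   accumulating transcripts), or `NA` when `C0` or all later abundances
#'   are unusable.
#' @export
estimate_kdecay <- function(abundances, timepoints_h) {
  stopifnot(length(abundances) == length(timepoints_h), any(timepoints_h == 0))
  c0 <- abundances[timepoints_h == 0][1]
  if (!is.finite(c0) || c0 <= 0) return(NA_real_)
  later <- timepoints_h > 0
  ct <- abundances[later]
  t <- timepoints_h[later]
  ok <- is.finite(ct) & ct > 0
  if (!any(ok)) return(NA_real_)
  mean(-log(ct[ok] / c0) / t[ok])
}

#' Half-life from a decay rate
#'
#' `t1/2 = ln(2) / K` for `K > 0`; non-positive rates have no finite
#' half-life and are censored (`NA`) rather than clipped, so they can be
#' excluded from rank statistics instead of fabricating infinities.
#'
#' @param kdecay_per_h Decay rate(s) in 1/h.
#' @return Half-life in hours, `NA` where censored.
#' @export
half_life <- function(kdecay_per_h) {
  ifelse(is.finite(kdecay_per_h) & kdecay_per_h > 0,
         log(2) / kdecay_per_h, NA_real_)
}

#' Full decay-kinetics pipeline on a time-course count matrix
#'
#' Per sample: CPM, spike-in calibration, conversion of gene CPM to
#' attomole. Per gene and condition: replicate-averaged attomole at each
#' timepoint, decay rate via [estimate_kdecay()], half-life via
#' [half_life()] (or, with `config$halflife_average = "halflife"`, the mean
#' of per-timepoint half-lives over timepoints with positive `K_t`).
#'
#' @param m A [count_matrix()] of genes plus spike-ins over a
#'   condition x timepoint x replicate design.
#' @param ref Spike-in reference table.
#' @param config An [analysis_config()] (calibration scale, averaging mode).
#' @return Data frame of class `"decay_estimates"`: `gene_id`, `condition`,
#'   `c0_attomole`, `k_per_h`, `halflife_h`, `censored`,
#'   `n_timepoints_used`.
#' @export
estimate_decay <- function(m, ref, config = analysis_config()) {
  stopifnot(inherits(m, "count_matrix"))
  fits <- fit_spikein_calibration(m, ref, scale = config$calibration_scale)
  cpm <- cpm_normalize(m)
  genes <- m$feature_kind == "gene"
  gene_ids <- rownames(m$counts)[genes]
  atto <- matrix(NA_real_, sum(genes), ncol(cpm),
                 dimnames = list(gene_ids, colnames(cpm)))
  for (j in seq_len(ncol(cpm))) {
    atto[, j] <- cpm_to_attomole(cpm[genes, j], fits[j, ],
                                 scale = config$calibration_scale)
  }
  timepoints <- sort(unique(m$samples$timepoint_h))
  if (!0 %in% timepoints) stop("time course must include t = 0")
  out <- list()
  for (cond in unique(m$samples$condition)) {
    prof <- vapply(timepoints, function(t) {
      sel <- m$samples$condition == cond & m$samples$timepoint_h == t
      rowMeans(atto[, sel, drop = FALSE], na.rm = TRUE)
    }, numeric(length(gene_ids)))
    prof <- matrix(prof, nrow = length(gene_ids))
    prof[!is.finite(prof)] <- NA_real_
    c0 <- prof[, timepoints == 0]
    later <- prof[, timepoints > 0, drop = FALSE]
    tl <- timepoints[timepoints > 0]
    kt <- -log(sweep(later, 1, c0, "/")) / rep(tl, each = nrow(later))
    kt[!is.finite(kt)] <- NA_real_
    n_used <- as.integer(is.finite(c0) & c0 > 0) + rowSums(is.finite(kt))
    k <- rowMeans(kt, na.rm = TRUE)
    k[!is.finite(c0) | c0 <= 0 | rowSums(is.finite(kt)) == 0] <- NA_real_
    k[!is.finite(k)] <- NA_real_
    if (config$halflife_average == "rate") {
      hl <- half_life(k)
    } else {
      ht <- half_life(kt)
      hl <- rowMeans(ht, na.rm = TRUE)
      hl[!is.finite(hl)] <- NA_real_
      hl[is.na(k)] <- NA_real_
    }
    out[[cond]] <- data.frame(
      gene_id = gene_ids,
      condition = cond,
      c0_attomole = c0,
      k_per_h = k,
      halflife_h = hl,
      censored = is.na(hl),
      n_timepoints_used = n_used,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("decay_estimates", "data.frame")
  res
}

#' Compare half-life distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test on uncensored half-lives of two groups
#' (two conditions, or two gene sets within a condition). Censored values
#' are excluded and their counts reported.
#'
#' @param hl_a,hl_b Numeric half-life vectors (`NA` = censored).
#' @param label_a,label_b Group labels for reporting.
#' @return List of class `"shift_result"`: labels, per-group `n` and
#'   `n_censored`, `median_a`, `median_b`, `delta_median`, `median_ratio`
#'   (b / a), `statistic`, `p_value`.
#' @export
compare_half_life_groups <- function(hl_a, hl_b,
                                     label_a = "a", label_b = "b") {
  a <- hl_a[is.finite(hl_a)]
  b <- hl_b[is.finite(hl_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 uncensored half-lives per group")
  }
  wt <- wilcoxon_ranksum(a, b)
  structure(list(
    labels = c(label_a, label_b),
    n = c(length(a), length(b)),
    n_censored = c(sum(!is.finite(hl_a)), sum(!is.finite(hl_b))),
    median_a = stats::median(a),
    median_b = stats::median(b),
    delta_median = stats::median(b) - stats::median(a),
    median_ratio = stats::median(b) / stats::median(a),
    statistic = wt$statistic,
    p_value = wt$p_value
  ), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("shift: %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("medians %.4g vs %.4g (delta %.4g), Wilcoxon p = %.3g\n",
              x$median_a, x$median_b, x$delta_median, x$p_value))
  invisible(x)
}
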