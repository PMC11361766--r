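#' Fit a nucleoside standard curve
#'
#' Ordinary least squares of measured signal on known concentration over
#' pure-standard points, as used to calibrate the MS channels before
#' forming an m6A/A ratio.
#'
#' @param concentration Known concentrations (>= 3 distinct positive
#'   values).
#' @param signal Measured signals, same length.
#' @param analyte Optional analyte label (e.g. "m6A" or "A").
#' @return List of class `"standard_curve"`: `analyte`, `slope`,
#'   `intercept`, `r_squared`, `n_points`. A flat signal yields slope 0 and
#'   r_squared 0 (degenerate but defined).
#' @export
fit_standard_curve <- function(concentration, signal, analyte = "") {
  stopifnot(length(concentration) == length(signal))
  if (length(unique(concentration)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  if (any(!is.finite(concentration) | concentration <= 0)) {
    stop("concentrations must be strictly positive")
  }
  slope <- stats::cov(concentration, signal) / stats::var(concentration)
  intercept <- mean(signal) - slope * mean(concentration)
  sst <- sum((signal - mean(signal))^2)
  ssr <- sum((signal - (intercept + slope * concentration))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r2, n_points = length(signal)),
            class = "standard_curve")
}

#' m6A/A ratio from calibrated MS signals
#'
#' Inverts each channel's standard curve
#' (`concentration = (signal - intercept) / slope`) and returns the ratio
#' of calibrated m6A to A concentrations. Both curves must have nonzero
#' slope and both calibrated concentrations must be positive (a signal
#' below the curve range has no valid concentration).
#'
#' @param signal_m6a,signal_a Measured signals of the two channels.
#' @param curve_m6a,curve_a [fit_standard_curve()] results.
#' @return The m6A/A concentration ratio.
#' @export
m6a_ratio <- function(signal_m6a, signal_a, curve_m6a, curve_a) {
  if (curve_m6a$slope == 0 || curve_a$slope == 0) {
    stop("standard curves must be invertible (nonzero slope)")
  }
  conc_m6a <- (signal_m6a - curve_m6a$intercept) / curve_m6a$slope
  conc_a <- (signal_a - curve_a$intercept) / curve_a$slope
  if (any(conc_m6a <= 0) || any(conc_a <= 0)) {
    stop("calibrated concentration is non-positive (signal below curve range)")
  }
  conc_m6a / conc_a
}

#' Proteomic z-score screen
#'
#' Removes proteins with more missing values than `max_missing`, optionally
#' divides each value by the protein's value in its batch's designated
#' control sample, z-scores each retained protein across all samples
#' (mean 0, sample sd 1 over available values), and compares the two
#' groups per protein with a two-sided Wilcoxon rank-sum test. Missing
#' values are never imputed. Proteins with zero variance are flagged and
#' excluded from testing.
#'
#' @param abundance Protein x sample numeric matrix (`NA` = missing), with
#'   row and column names.
#' @param groups Character vector per sample, values `"control"` /
#'   `"patient"` (or any two labels).
#' @param max_missing Maximum tolerated number of missing values per
#'   protein (default 4; proteins with *more* are removed).
#' @param batch Optional character vector per sample.
#' @param batch_control Named character vector mapping each batch to the
#'   `colnames` id of its control sample; required when `batch` is given.
#' @param log_scale Divide on the log scale (i.e. subtract the control's
#'   log2 value) instead of the linear scale (default FALSE).
#' @return List with `z` (z-score matrix over retained, testable proteins),
#'   `test` (data frame `protein_id`, `n_missing`, `p`, `padj`,
#'   `zero_variance`), and `removed` (ids dropped by the missingness
#'   filter).
#' @export
proteomics_screen <- function(abundance, groups, max_missing = 4,
                              batch = NULL, batch_control = NULL,
                              log_scale = FALSE) {
  mat <- as.matrix(abundance)
  stopifnot(length(groups) == ncol(mat))
  lv <- unique(groups)
  if (length(lv) != 2) stop("groups must have exactly two levels")
  n_missing <- rowSums(is.na(mat))
  removed <- rownames(mat)[n_missing > max_missing]
  keep <- n_missing <= max_missing
  mat <- mat[keep, , drop = FALSE]
  n_missing <- n_missing[keep]
  if (!is.null(batch)) {
    if (is.null(batch_control)) stop("batch normalization needs batch_control")
    for (b in unique(batch)) {
      ctrl_id <- batch_control[[b]]
      if (is.null(ctrl_id) || !ctrl_id %in% colnames(mat)) {
        stop(sprintf("batch '%s' has no designated control sample", b))
      }
      cols <- batch == b
      if (log_scale) {
        mat[, cols] <- log2(mat[, cols, drop = FALSE]) - log2(mat[, ctrl_id])
      } else {
        mat[, cols] <- mat[, cols, drop = FALSE] / mat[, ctrl_id]
      }
    }
  }
  mu <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
  zero_var <- !is.finite(sdv) | sdv == 0
  z <- (mat - mu) / sdv
  p <- rep(NA_real_, nrow(mat))
  g1 <- groups == lv[1]
  for (i in which(!zero_var)) {
    zi <- z[i, ]
    a <- zi[g1 & !is.na(zi)]
    b <- zi[!g1 & !is.na(zi)]
    if (length(a) >= 1 && length(b) >= 1) {
      p[i] <- wilcoxon_ranksum(a, b)$p_value
    }
  }
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  list(
    z = z[!zero_var, , drop = FALSE],
    test = data.frame(protein_id = rownames(mat), n_missing = n_missing,
                      p = p, padj = padj, zero_variance = zero_var,
                      stringsAsFactors = FALSE),
    removed = removed
  )
}
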