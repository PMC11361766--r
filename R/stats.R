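# shared combination cache for the exact rank-sum enumeration
.ranksum_cache <- new.env(parent = emptyenv())

.ranksum_combinations <- function(n_total, n1) {
  key <- paste(n_total, n1, sep = "_")
  if (is.null(.ranksum_cache[[key]])) {
    .ranksum_cache[[key]] <- utils::combn(n_total, n1)
  }
  .ranksum_cache[[key]]
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test. For combined sample sizes up to
#' `exact_max_n` the p-value is computed by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments (valid in the presence of ties,
#' where the classical exact distribution is not); beyond that, the normal
#' approximation with tie correction and continuity correction is used.
#'
#' The two-sided exact p-value is the permutation probability of a rank sum
#' at least as far from its null expectation as the observed one.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max_n Combined-size limit for exact enumeration (default 20).
#' @return List with `statistic` (Mann-Whitney U, as in [stats::wilcox.test()]),
#'   `p_value`, and `method` ("exact" or "normal").
#' @export
wilcoxon_ranksum <- function(x, y, exact_max_n = 20) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be nonempty")
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])          # rank sum of x
  mu <- n1 * (n + 1) / 2
  if (n <= exact_max_n) {
    idx <- .ranksum_combinations(n, n1)
    w_perm <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(w_perm - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(statistic = w - n1 * (n1 + 1) / 2, p_value = p, method = method)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table. The reported odds ratio is
#' the sample odds ratio ad/bc (not the conditional MLE), with an infinite
#' flag when bc = 0.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (may be `Inf`), `p_value`, and `table`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(!is.finite(tab) | tab < 0 | tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (sum(tab) == 0) stop("all-zero table: no observations to test")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

# vectorized Welch t-test across rows of two matrices (genes x replicates)
.welch_t_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- if (na > 1) rowSums((xa - ma)^2) / (na - 1) else rep(NA_real_, nrow(xa))
  vb <- if (nb > 1) rowSums((xb - mb)^2) / (nb - 1) else rep(NA_real_, nrow(xb))
  se2 <- va / na + vb / nb
  diff <- mb - ma
  t <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero variance in both groups
  degen <- is.finite(se2) & se2 == 0
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- 0
  t[degen & diff == 0] <- 0
  p[is.na(p)] <- 1
  list(diff = diff, t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}
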