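# small in-code fixtures shared across test files

# minimal count matrix: counts is a features x samples matrix (or vector of
# column values), metadata derived from the sample ids
make_cm <- function(counts, condition = NULL, assay = NULL,
                    timepoint_h = NULL, replicate = NULL,
                    feature_kind = "gene") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  ns <- ncol(counts)
  meta <- data.frame(
    sample_id = colnames(counts),
    condition = if (is.null(condition)) "control" else condition,
    assay = if (is.null(assay)) "input" else assay,
    timepoint_h = if (is.null(timepoint_h)) NA_real_ else timepoint_h,
    replicate = if (is.null(replicate)) seq_len(ns) else replicate,
    stringsAsFactors = FALSE
  )
  count_matrix(counts, meta, feature_kind = feature_kind)
}

# one-gene ground-truth record for hand-built decay fixtures
make_gt <- function(gene_id = "g1", m = 0.5, k_control = 0.2,
                    k_patient = k_control, c0 = 100, target = TRUE) {
  n <- length(gene_id)
  structure(data.frame(
    gene_id = gene_id,
    m_control = rep_len(m, n),
    m_patient = rep_len(m, n),
    is_hypo = rep_len(k_patient < k_control, n),
    is_reader_target = rep_len(target, n),
    k_control = rep_len(k_control, n),
    k_patient = rep_len(k_patient, n),
    baseline_attomole = rep_len(c0, n),
    baseline_attomole_patient = rep_len(c0, n) *
      rep_len(k_control, n) / rep_len(k_patient, n),
    stringsAsFactors = FALSE
  ), class = c("ground_truth", "data.frame"))
}

# independent brute-force oracles --------------------------------------------

# Benjamini-Hochberg step-up, straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(ps[i:n] * n / (i:n))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher p by hypergeometric enumeration (probability-mass rule)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# two-sided rank-sum p by explicit permutation enumeration
ranksum_oracle <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  mu <- n1 * (length(v) + 1) / 2
  wobs <- sum(r[seq_len(n1)])
  idx <- combn(length(v), n1)
  wp <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(wp - mu) >= abs(wobs - mu) - 1e-9)
}
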