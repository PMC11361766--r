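#' IP-vs-input enrichment per feature
#'
#' Depth-normalized m6A enrichment for one condition: counts are CPM
#' normalized per library, averaged across the condition's replicates
#' within each assay, and the log2 ratio of pooled IP to pooled input
#' proportions is taken with a pseudocount. Enrichment is 0 wherever IP and
#' input proportions coincide, and is invariant to rescaling any library's
#' depth.
#'
#' @param m A [count_matrix()] containing IP and input samples.
#' @param condition Condition label to quantify.
#' @param pseudocount Added to both pooled CPM values (default 0.5).
#' @return Data frame with `feature_id`, `log2_enrichment`, `ip_pooled`,
#'   `input_pooled` (pooled raw counts).
#' @export
compute_enrichment <- function(m, condition, pseudocount = 0.5) {
  stopifnot(inherits(m, "count_matrix"))
  sel <- m$samples$condition == condition
  ip <- sel & m$samples$assay == "IP"
  input <- sel & m$samples$assay == "input"
  if (!any(ip) || !any(input)) {
    stop(sprintf("condition '%s' needs at least one IP and one input sample",
                 condition))
  }
  cpm <- cpm_normalize(m)
  ip_cpm <- rowMeans(cpm[, ip, drop = FALSE])
  input_cpm <- rowMeans(cpm[, input, drop = FALSE])
  data.frame(
    feature_id = rownames(m$counts),
    log2_enrichment = log2((ip_cpm + pseudocount) / (input_cpm + pseudocount)),
    ip_pooled = rowSums(m$counts[, ip, drop = FALSE]),
    input_pooled = rowSums(m$counts[, input, drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' Features significant in enough replicates
#'
#' Replicate-consistency rule for significance: a feature is retained when
#' its per-replicate q-value is strictly below `q_threshold` in at least
#' `min_replicates` replicates.
#'
#' @param q Numeric matrix of per-replicate q-values (features x replicates,
#'   feature ids as row names).
#' @param q_threshold Strict significance threshold (default 0.01).
#' @param min_replicates Minimum number of qualifying replicates
#'   (default 3).
#' @return Character vector of qualifying feature ids.
#' @export
significant_features <- function(q, q_threshold = 0.01, min_replicates = 3) {
  q <- as.matrix(q)
  if (min_replicates > ncol(q)) {
    stop("min_replicates exceeds the number of replicates")
  }
  if (is.null(rownames(q))) stop("q-value matrix needs feature ids as row names")
  rownames(q)[rowSums(q < q_threshold, na.rm = TRUE) >= min_replicates]
}

#' Differential methylation between two conditions
#'
#' Tests, per feature, whether the IP-vs-input log-odds differ between
#' conditions. Pooled, depth-normalized counts (replicate-mean CPM rescaled
#' to the pooled library size of each condition x assay class) enter a
#' two-proportion z-test with pseudocount; p-values are BH adjusted and
#' features are classified `hypo` (FDR below threshold, negative delta),
#' `hyper` (positive delta) or `unchanged`.
#'
#' Because differential methylation changes the composition of the IP
#' library (a large hypomethylated cohort shrinks everyone else's share),
#' the per-feature delta log-odds is median-centered before testing --
#' equivalently, the second condition's IP library is rescaled so the
#' median feature shows no change. This assumes most features are
#' unchanged, the same assumption behind median-of-ratios normalization.
#'
#' @param m A [count_matrix()] with IP and input samples in both conditions.
#' @param cond_a,cond_b Condition labels (delta is `cond_b` minus `cond_a`).
#' @param config An [analysis_config()].
#' @return Data frame of class `"methylation_calls"`: `feature_id`,
#'   `enrich_<cond_a>`, `enrich_<cond_b>`, `delta_log2`, `p`, `fdr`,
#'   `class`, `replicate_support`. Features with zero pooled input in both
#'   conditions are dropped with a message.
#' @export
differential_methylation <- function(m, cond_a = "control", cond_b = "patient",
                                     config = analysis_config()) {
  stopifnot(inherits(m, "count_matrix"))
  pc <- config$pseudocount
  cpm <- cpm_normalize(m)

  pooled <- function(cond, assay) {
    sel <- m$samples$condition == cond & m$samples$assay == assay
    if (!any(sel)) stop(sprintf("no %s samples for condition '%s'", assay, cond))
    mean_cpm <- rowMeans(cpm[, sel, drop = FALSE])
    total <- sum(m$counts[, sel, drop = FALSE])
    mean_cpm / 1e6 * total   # effective pooled counts at the class depth
  }
  ip_a <- pooled(cond_a, "IP");    in_a <- pooled(cond_a, "input")
  ip_b <- pooled(cond_b, "IP");    in_b <- pooled(cond_b, "input")

  drop <- in_a + in_b == 0
  if (any(drop)) {
    message(sprintf("dropping %d feature(s) with zero pooled input in both conditions",
                    sum(drop)))
  }
  keep <- !drop
  fid <- rownames(m$counts)[keep]
  ip_a <- ip_a[keep]; in_a <- in_a[keep]; ip_b <- ip_b[keep]; in_b <- in_b[keep]

  delta_raw <- log2(((ip_b + pc) / (in_b + pc)) / ((ip_a + pc) / (in_a + pc)))
  med <- stats::median(delta_raw)
  ip_b <- ip_b * 2^(-med)          # composition correction on cond_b's IP library

  delta <- log2(((ip_b + pc) / (in_b + pc)) / ((ip_a + pc) / (in_a + pc)))
  a <- ip_a + pc; b <- in_a + pc; cc <- ip_b + pc; d <- in_b + pc
  p1 <- a / (a + b)
  p2 <- cc / (cc + d)
  pp <- (a + cc) / (a + b + cc + d)
  se <- sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (cc + d)))
  z <- ifelse(se > 0, (p2 - p1) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_adjust(p)
  class <- rep("unchanged", length(p))
  class[fdr < config$fdr_methylation & delta < 0] <- "hypo"
  class[fdr < config$fdr_methylation & delta > 0] <- "hyper"

  support <- .replicate_support(m, cond_a, cond_b, keep, med, pc, sign(delta))

  # per-condition enrichment on the CPM scale, consistent with compute_enrichment
  ea <- compute_enrichment(m, cond_a, pc)$log2_enrichment[keep]
  eb <- compute_enrichment(m, cond_b, pc)$log2_enrichment[keep]

  out <- data.frame(feature_id = fid, stringsAsFactors = FALSE)
  out[[paste0("enrich_", cond_a)]] <- ea
  out[[paste0("enrich_", cond_b)]] <- eb
  out$delta_log2 <- delta
  out$p <- p
  out$fdr <- fdr
  out$class <- class
  out$replicate_support <- support
  class(out) <- c("methylation_calls", "data.frame")
  attr(out, "conditions") <- c(cond_a, cond_b)
  attr(out, "fdr_threshold") <- config$fdr_methylation
  out
}

# number of replicate pairs whose individual delta log-odds agrees in sign
# with the pooled call
.replicate_support <- function(m, cond_a, cond_b, keep, med, pc, pooled_sign) {
  cpm <- cpm_normalize(m)
  reps <- intersect(
    m$samples$replicate[m$samples$condition == cond_a & m$samples$assay == "IP"],
    m$samples$replicate[m$samples$condition == cond_b & m$samples$assay == "IP"]
  )
  support <- rep(0L, sum(keep))
  for (r in reps) {
    col <- function(cond, assay) {
      sel <- m$samples$condition == cond & m$samples$assay == assay &
        m$samples$replicate == r
      if (!any(sel)) return(NULL)
      rowMeans(cpm[, sel, drop = FALSE])[keep]
    }
    ia <- col(cond_a, "IP"); na <- col(cond_a, "input")
    ib <- col(cond_b, "IP"); nb <- col(cond_b, "input")
    if (is.null(ia) || is.null(na) || is.null(ib) || is.null(nb)) next
    d_r <- log2(((ib + pc) / (nb + pc)) / ((ia + pc) / (na + pc))) - med
    support <- support + as.integer(sign(d_r) == pooled_sign)
  }
  support
}

#' Gene-level methylation class from peak-level calls
#'
#' A gene is hypomethylated when at least one of its peaks is; otherwise it
#' is non-hypomethylated. With `nonhypo_includes_hyper = FALSE` in the
#' config used downstream, hyper-only genes can be excluded from the
#' comparison group by the caller; the partition returned here always
#' covers all mapped genes.
#'
#' @param calls A `"methylation_calls"` data frame (per peak).
#' @param peak_to_gene Data frame with columns `peak_id`, `gene_id`
#'   covering every peak, or `NULL` when features already are genes
#'   (identity mapping).
#' @return Data frame with `gene_id`, `class` (`"hypo"` / `"nonhypo"`),
#'   `n_peaks`, `n_hypo_peaks`, `any_hyper`.
#' @export
classify_genes <- function(calls, peak_to_gene = NULL) {
  if (is.null(peak_to_gene)) {
    peak_to_gene <- data.frame(peak_id = calls$feature_id,
                               gene_id = calls$feature_id,
                               stringsAsFactors = FALSE)
  }
  unmapped <- setdiff(calls$feature_id, peak_to_gene$peak_id)
  if (length(unmapped) > 0) {
    stop("unmapped peak id(s): ", paste(utils::head(unmapped, 10), collapse = ", "))
  }
  gene <- peak_to_gene$gene_id[match(calls$feature_id, peak_to_gene$peak_id)]
  agg <- function(v) tapply(v, gene, FUN = sum)
  n_peaks <- as.integer(table(gene))
  gene_ids <- names(table(gene))
  n_hypo <- as.integer(agg(calls$class == "hypo")[gene_ids])
  n_hyper <- as.integer(agg(calls$class == "hyper")[gene_ids])
  data.frame(
    gene_id = gene_ids,
    class = ifelse(n_hypo > 0, "hypo", "nonhypo"),
    n_peaks = n_peaks,
    n_hypo_peaks = n_hypo,
    any_hyper = n_hyper > 0,
    stringsAsFactors = FALSE
  )
}

#' Spike-normalized MeRIP-qPCR fold enrichment
#'
#' Fold enrichment of a target in the IP fraction over input, normalizing
#' each fraction to a spiked-in reference RNA:
#' `2^-[(Ct_IP,target - Ct_IP,spike) - (Ct_input,target - Ct_input,spike)]`.
#' Equal spike-normalized Ct in IP and input gives 1.
#'
#' @param ct_ip_target,ct_ip_spike,ct_input_target,ct_input_spike Finite
#'   qPCR cycle-threshold values (vectorized).
#' @return Positive fold enrichment.
#' @export
merip_qpcr_fold_enrichment <- function(ct_ip_target, ct_ip_spike,
                                       ct_input_target, ct_input_spike) {
  stopifnot(all(is.finite(c(ct_ip_target, ct_ip_spike,
                            ct_input_target, ct_input_spike))))
  2^-((ct_ip_target - ct_ip_spike) - (ct_input_target - ct_input_spike))
}
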