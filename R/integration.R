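#' Call reader target genes from RIP-seq counts
#'
#' Applies the expression pre-filter, then tests each gene for RIP-vs-input
#' enrichment; targets are the genes significantly *upregulated* in the RIP
#' fraction: adjusted p strictly below `config$padj_targets` and positive
#' log2 fold change.
#'
#' The default `method = "paired"` exploits the matched design (each RIP
#' library is the immunoprecipitated fraction of the same lysate as its
#' input library): the per-replicate log2 RIP/input ratio of depth
#' normalized counts, median-centered per replicate to absorb the global
#' enrichment of bound transcripts, is tested against zero with a
#' one-sample t-test across replicates. `method = "unpaired"` instead
#' treats RIP and input as independent groups through the same Welch-t core
#' as [differential_expression()].
#'
#' @param m A [count_matrix()] with `assay` values `"RIP"` and `"input"`.
#' @param config An [analysis_config()].
#' @param label Name of the reader for reporting (default "reader").
#' @param method `"paired"` (default) or `"unpaired"`, see Details.
#' @return List of class `"target_set"`: `label`, `genes` (character),
#'   `thresholds`, and `table` (the underlying per-gene test results with
#'   `log2fc`, `p`, `padj`).
#' @export
call_rip_targets <- function(m, config = analysis_config(), label = "reader",
                             method = c("paired", "unpaired")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "count_matrix"))
  n_rip <- sum(m$samples$assay == "RIP")
  n_in <- sum(m$samples$assay == "input")
  if (n_rip < 2 || n_in < 2) {
    stop("need at least 2 RIP and 2 input replicates")
  }
  use <- m$samples$assay %in% c("RIP", "input")
  m2 <- m[, use]
  if (method == "paired") {
    tab <- .rip_paired_test(m2, config)
  } else {
    tab <- .de_core(m2, m2$samples$assay, "input", "RIP", config)
    names(tab)[names(tab) == "mean_norm_a"] <- "mean_norm_input"
    names(tab)[names(tab) == "mean_norm_b"] <- "mean_norm_rip"
  }
  genes <- tab$gene_id[tab$padj < config$padj_targets & tab$log2fc > 0]
  structure(list(
    label = label,
    genes = genes,
    thresholds = list(padj = config$padj_targets,
                      min_count = config$min_count,
                      min_samples = config$min_samples),
    table = tab
  ), class = "target_set")
}

# paired RIP/input enrichment: per-replicate log2 ratio of CPM with
# pseudocount, median-centered per replicate, one-sample t across replicates
.rip_paired_test <- function(m, config) {
  mf <- filter_low_expression(m, config$min_count, config$min_samples)
  if (nrow(mf$counts) == 0) stop("no features pass the expression filter")
  cpm <- cpm_normalize(mf)
  reps <- sort(intersect(mf$samples$replicate[mf$samples$assay == "RIP"],
                         mf$samples$replicate[mf$samples$assay == "input"]))
  if (length(reps) < 2) stop("paired test needs >= 2 matched replicate pairs")
  ratios <- vapply(reps, function(r) {
    rip <- mf$samples$assay == "RIP" & mf$samples$replicate == r
    inp <- mf$samples$assay == "input" & mf$samples$replicate == r
    d <- log2((rowMeans(cpm[, rip, drop = FALSE]) + config$pseudocount) /
                (rowMeans(cpm[, inp, drop = FALSE]) + config$pseudocount))
    d - stats::median(d)
  }, numeric(nrow(mf$counts)))
  ratios <- matrix(ratios, nrow = nrow(mf$counts))
  n <- ncol(ratios)
  mu <- rowMeans(ratios)
  sdv <- sqrt(rowSums((ratios - mu)^2) / (n - 1))
  t <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[!is.finite(p)] <- 1
  data.frame(
    gene_id = rownames(mf$counts),
    log2fc = mu,
    p = p,
    padj = bh_adjust(p),
    mean_norm_input = rowMeans(cpm[, mf$samples$assay == "input", drop = FALSE]),
    mean_norm_rip = rowMeans(cpm[, mf$samples$assay == "RIP", drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set '%s': %d genes (padj < %g, log2fc > 0)\n",
              x$label, length(x$genes), x$thresholds$padj))
  invisible(x)
}

#' Overlap enrichment between two gene sets
#'
#' Builds the 2x2 membership table of two sets over a stated gene universe
#' and applies [fisher_exact_2x2()] (two-tailed). Both sets must be subsets
#' of the universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector defining the background.
#' @param labels Length-2 labels for reporting.
#' @return List of class `"overlap_result"`: `labels`, `table` (2x2:
#'   rows = in/out of `set_a`, columns = in/out of `set_b`),
#'   `odds_ratio`, `p_value`, `universe_size`, `n_overlap`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe,
                               labels = c("set_a", "set_b")) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) > 0 || length(out_b) > 0) {
    stop("set element(s) outside the universe: ",
         paste(utils::head(c(out_a, out_b), 10), collapse = ", "))
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_a", "out_a"), c("in_b", "out_b")))
  ft <- fisher_exact_2x2(tab)
  structure(list(
    labels = labels,
    table = tab,
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value,
    universe_size = length(universe),
    n_overlap = tab[1, 1]
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s x %s over %d genes: %d shared, OR = %.3g, Fisher p = %.3g\n",
              x$labels[1], x$labels[2], x$universe_size, x$n_overlap,
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Consolidated per-gene report and headline statistics
#'
#' Joins methylation class, expression fold change, condition-wise
#' half-lives and reader-target membership into one table, and computes the
#' three headline statistics of the analysis: the expression shift of hypo
#' versus non-hypo genes, the half-life shift of hypo genes between
#' conditions, and the hypo / reader-target overlap enrichment.
#'
#' @param calls A `"methylation_calls"` data frame at gene level (features
#'   are genes, or pass peak-level calls through [classify_genes()] and
#'   supply `gene_class`).
#' @param de A `"diff_expr"` data frame (patient vs control).
#' @param hl A `"decay_estimates"` data frame covering both conditions.
#' @param targets A `"target_set"` (may hold zero genes).
#' @param gene_class Optional data frame from [classify_genes()]; derived
#'   from `calls` when omitted.
#' @param config An [analysis_config()]; with
#'   `nonhypo_includes_hyper = FALSE` hypermethylated genes are excluded
#'   from the non-hypo comparison group.
#' @return List of class `"integration_report"` with `table` (one row per
#'   detected gene) and `summary` (list with `expression_shift`,
#'   `halflife_shift`, `target_overlap`; an empty target set yields
#'   `target_overlap = NULL` with a note).
#' @export
integrate_report <- function(calls, de, hl, targets, gene_class = NULL,
                             config = analysis_config()) {
  if (is.null(gene_class)) gene_class <- classify_genes(calls)
  for (nm in c("gene_class", "de")) {
    ids <- get(nm)$gene_id
    if (anyDuplicated(ids)) stop("duplicate gene ids in ", nm)
  }
  conds <- unique(hl$condition)
  if (length(conds) != 2) stop("half-life estimates must cover two conditions")
  hl_a <- hl[hl$condition == conds[1], ]
  hl_b <- hl[hl$condition == conds[2], ]
  if (anyDuplicated(hl_a$gene_id) || anyDuplicated(hl_b$gene_id)) {
    stop("duplicate gene ids in hl")
  }

  genes <- sort(de$gene_id)
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  tab$meth_class <- gene_class$class[match(genes, gene_class$gene_id)]
  tab$log2fc <- de$log2fc[match(genes, de$gene_id)]
  tab$padj <- de$padj[match(genes, de$gene_id)]
  tab[[paste0("halflife_", conds[1])]] <- hl_a$halflife_h[match(genes, hl_a$gene_id)]
  tab[[paste0("halflife_", conds[2])]] <- hl_b$halflife_h[match(genes, hl_b$gene_id)]
  tab$delta_halflife <- tab[[paste0("halflife_", conds[2])]] -
    tab[[paste0("halflife_", conds[1])]]
  tab$is_target <- genes %in% targets$genes

  hypo_genes <- gene_class$gene_id[gene_class$class == "hypo"]
  de_use <- de
  if (!config$nonhypo_includes_hyper) {
    hyper_only <- gene_class$gene_id[gene_class$class != "hypo" & gene_class$any_hyper]
    de_use <- de[!de$gene_id %in% hyper_only, ]
  }
  expression_shift <- group_shift_test(de_use, hypo_genes)

  hypo_a <- hl_a$halflife_h[hl_a$gene_id %in% hypo_genes]
  hypo_b <- hl_b$halflife_h[hl_b$gene_id %in% hypo_genes]
  halflife_shift <- compare_half_life_groups(hypo_a, hypo_b,
                                             label_a = conds[1],
                                             label_b = conds[2])

  target_overlap <- NULL
  overlap_note <- NULL
  if (length(targets$genes) > 0) {
    universe <- de$gene_id
    target_overlap <- overlap_enrichment(intersect(hypo_genes, universe),
                                         intersect(targets$genes, universe),
                                         universe,
                                         labels = c("hypo", targets$label))
  } else {
    overlap_note <- "target set empty; overlap enrichment not computable"
  }

  structure(list(
    table = tab,
    summary = list(expression_shift = expression_shift,
                   halflife_shift = halflife_shift,
                   target_overlap = target_overlap,
                   note = overlap_note)
  ), class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat(sprintf("integration_report: %d genes\n", nrow(x$table)))
  s <- x$summary
  cat(sprintf("expression shift (hypo vs non-hypo): delta median log2fc = %.3g, p = %.3g\n",
              s$expression_shift$delta_median, s$expression_shift$p_value))
  cat(sprintf("half-life shift (hypo genes, %s vs %s): median ratio = %.3g, p = %.3g\n",
              s$halflife_shift$labels[2], s$halflife_shift$labels[1],
              s$halflife_shift$median_ratio, s$halflife_shift$p_value))
  if (!is.null(s$target_overlap)) {
    cat(sprintf("hypo x target overlap: %d shared, OR = %.3g, Fisher p = %.3g\n",
                s$target_overlap$n_overlap, s$target_overlap$odds_ratio,
                s$target_overlap$p_value))
  } else {
    cat(s$note, "\n")
  }
  invisible(x)
}
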