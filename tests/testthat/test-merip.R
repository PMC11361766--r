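# mirrored-pair fixture: featA hypomethylated in patient, featB the mirror
# image, fillers identical everywhere; all four library totals are equal so
# CPM equals raw counts up to one factor and the composition median is zero
merip_fixture <- function() {
  counts <- rbind(
    featA = c(800, 200, 200, 800),
    featB = c(200, 800, 800, 200),
    matrix(500, nrow = 10, ncol = 4,
           dimnames = list(sprintf("fill%02d", 1:10), NULL))
  )
  colnames(counts) <- c("ctrl_IP", "ctrl_in", "pat_IP", "pat_in")
  make_cm(counts,
          condition = c("control", "control", "patient", "patient"),
          assay = c("IP", "input", "IP", "input"),
          replicate = 1)
}

test_that("enrichment is the depth-normalized IP/input log ratio", {
  cm <- make_cm(rbind(a = c(80, 20), b = c(20, 80)),
                assay = c("IP", "input"), replicate = 1)
  e <- compute_enrichment(cm, "control", pseudocount = 0)
  expect_equal(e$log2_enrichment, c(2, -2))
  expect_equal(e$ip_pooled, c(80, 20))
  # rescaling the IP library 10x changes nothing
  cm10 <- make_cm(rbind(a = c(800, 20), b = c(200, 80)),
                  assay = c("IP", "input"), replicate = 1)
  expect_equal(compute_enrichment(cm10, "control", 0)$log2_enrichment, c(2, -2))
  # identical proportions -> zero everywhere
  cm0 <- make_cm(rbind(a = c(30, 60), b = c(70, 140)),
                 assay = c("IP", "input"), replicate = 1)
  expect_equal(compute_enrichment(cm0, "control", 0)$log2_enrichment, c(0, 0))
  expect_error(compute_enrichment(cm0, "patient"), "patient")
})

test_that("replicate-consistency rule uses strict inequality", {
  q <- rbind(f1 = c(0.001, 0.005, 0.0099, 0.5),
             f2 = c(0.001, 0.005, 0.5, 0.5),
             f3 = c(0.01, 0.01, 0.01, 0.01))   # exactly at threshold
  expect_equal(significant_features(q, 0.01, 3), "f1")
  expect_error(significant_features(q, 0.01, 5), "replicates")
})

test_that("differential methylation recovers the pooled 2x2 contrast", {
  calls <- differential_methylation(merip_fixture(), "control", "patient",
                                    analysis_config())
  a <- calls[calls$feature_id == "featA", ]
  expect_equal(a$class, "hypo")
  expect_equal(a$delta_log2, -4, tolerance = 0.01)
  expect_equal(calls[calls$feature_id == "featB", "class"], "hyper")
  expect_true(all(calls$class[grepl("fill", calls$feature_id)] == "unchanged"))
  # z-test p agrees with a Fisher exact oracle on the pooled table in
  # order of magnitude (both are far in the tail)
  pf <- fisher_oracle(matrix(c(800, 200, 200, 800), 2, byrow = TRUE))
  expect_lt(abs(log10(a$p) - log10(pf)) / abs(log10(pf)), 0.15)
  expect_equal(a$replicate_support, 1L)
})

test_that("identical conditions give a flat null", {
  counts <- rbind(matrix(c(300, 100), 5, 2, byrow = TRUE,
                         dimnames = list(sprintf("g%d", 1:5), NULL)))
  cm <- make_cm(cbind(counts, counts),
                condition = rep(c("control", "patient"), each = 2),
                assay = rep(c("IP", "input"), 2), replicate = 1)
  calls <- differential_methylation(cm, "control", "patient", analysis_config())
  expect_equal(calls$delta_log2, rep(0, 5))
  expect_equal(calls$p, rep(1, 5))
  expect_true(all(calls$class == "unchanged"))
})

test_that("gene classification follows the any-hypo-peak rule", {
  calls <- data.frame(
    feature_id = c("p1", "p2", "p3", "p4", "p5"),
    class = c("hypo", "unchanged", "unchanged", "hyper", "unchanged"),
    stringsAsFactors = FALSE
  )
  map <- data.frame(peak_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_id = c("gA", "gA", "gB", "gC", "gC"),
                    stringsAsFactors = FALSE)
  cls <- classify_genes(calls, map)
  expect_equal(cls$class[cls$gene_id == "gA"], "hypo")
  expect_equal(cls$class[cls$gene_id == "gB"], "nonhypo")
  expect_equal(cls$class[cls$gene_id == "gC"], "nonhypo")
  expect_true(cls$any_hyper[cls$gene_id == "gC"])
  # partition: every gene lands in exactly one class
  expect_equal(sum(cls$class == "hypo") + sum(cls$class == "nonhypo"), 3)
  expect_error(classify_genes(calls, map[-1, ]), "p1")
})

test_that("spike-normalized MeRIP-qPCR fold enrichment", {
  expect_equal(merip_qpcr_fold_enrichment(20, 18, 24, 18), 16)
  expect_equal(merip_qpcr_fold_enrichment(20, 20, 20, 20), 1)
  base <- merip_qpcr_fold_enrichment(20, 18, 24, 18)
  expect_equal(merip_qpcr_fold_enrichment(21, 18, 24, 18), base / 2)
})
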