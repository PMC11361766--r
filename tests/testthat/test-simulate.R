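test_that("ground truth respects its construction invariants", {
  p <- simulation_params(n_genes = 500, seed = 4)
  gt <- simulate_transcriptome(p)
  expect_identical(gt, simulate_transcriptome(p))  # determinism
  meth <- gt$m_control > 0
  expect_equal(sum(gt$is_hypo), round(p$hypo_fraction * sum(meth)))
  expect_true(all(gt$m_patient[gt$is_hypo] < gt$m_control[gt$is_hypo]))
  expect_true(all(gt$m_patient[!gt$is_hypo] == gt$m_control[!gt$is_hypo]))
  # K differs exactly for hypo reader targets, equal otherwise
  aff <- gt$is_hypo & gt$is_reader_target
  expect_true(all(gt$k_patient[aff] < gt$k_control[aff]))
  expect_true(all(gt$k_patient[!aff] == gt$k_control[!aff]))
  # stabilization propagates to the patient steady state
  expect_true(all(gt$baseline_attomole_patient[aff] > gt$baseline_attomole[aff]))

  # no-effect nulls
  gt0 <- simulate_transcriptome(simulation_params(n_genes = 200, hypo_fraction = 0, seed = 4))
  expect_true(all(gt0$k_patient == gt0$k_control))
  gt1 <- simulate_transcriptome(simulation_params(n_genes = 200, hypo_effect = 1, seed = 4))
  expect_false(any(gt1$is_hypo))
  expect_true(all(gt1$m_patient == gt1$m_control))
})

test_that("generators emit valid, reproducible count matrices", {
  p <- simulation_params(n_genes = 60, n_spikes = 10, depth_mean = 5e4, seed = 9)
  gt <- simulate_transcriptome(p)
  for (f in list(simulate_merip_counts, simulate_rip_counts)) {
    cm <- f(gt, p)
    expect_silent(validate_count_matrix(cm))
    expect_identical(cm$counts, f(gt, p)$counts)
  }
  dm <- simulate_decay_timecourse(gt, p)
  expect_silent(validate_count_matrix(dm))
  expect_equal(sum(dm$feature_kind == "spikein"), 10)
  expect_equal(ncol(dm$counts), 2 * 3 * 3)  # condition x timepoint x replicate
})

test_that("mean IP counts match the stated formula (Monte Carlo)", {
  n_sim <- 400
  p1 <- simulation_params(n_genes = 20, n_spikes = 3, depth_mean = 5e4,
                          replicates_per_condition = 1, seed = 1)
  gt <- simulate_transcriptome(p1)
  w <- gt$baseline_attomole * (1 + p1$ip_gain * gt$m_control)
  mu <- p1$depth_mean * w / sum(w)
  sims <- sapply(seq_len(n_sim), function(s) {
    ps <- simulation_params(n_genes = 20, n_spikes = 3, depth_mean = 5e4,
                            replicates_per_condition = 1, seed = 1000 + s)
    simulate_merip_counts(gt, ps)$counts[, "control_IP_r1"]
  })
  emp_mean <- rowMeans(sims)
  emp_se <- apply(sims, 1, sd) / sqrt(n_sim)
  within3 <- abs(emp_mean - mu) <= 3 * emp_se
  expect_gte(sum(within3), 19)  # 3-sigma band, allow one excursion in 20
})

test_that("noiseless decay counts follow the exponential exactly", {
  # K = ln2/3 per hour, C0 = 100 -> abundances 100, 50, 25 at t = 0, 3, 6
  p <- simulation_params(n_genes = 2, n_spikes = 5, depth_cv = 0, seed = 2)
  gt <- make_gt(gene_id = c("g1", "g2"), k_control = log(2) / 3, c0 = c(100, 40))
  dm <- simulate_decay_timecourse(gt, p, noiseless = TRUE)
  cpm <- cpm_normalize(dm)
  ctrl <- dm$samples$condition == "control"
  ts <- dm$samples$timepoint_h[ctrl]
  # within each sample counts are proportional to abundance: g1 share halves
  # every 3 h relative to the constant spikes
  rel <- cpm["g1", ctrl] / cpm["SPIKE-001", ctrl]
  rel0 <- rel[ts == 0][1]
  expect_equal(unname(rel[ts == 3] / rel0), rep(0.5, sum(ts == 3)), tolerance = 1e-12)
  expect_equal(unname(rel[ts == 6] / rel0), rep(0.25, sum(ts == 6)), tolerance = 1e-12)
})

test_that("zero decay gives constant abundance and constant spike counts", {
  p <- simulation_params(n_genes = 3, n_spikes = 5, depth_cv = 0, seed = 2)
  gt <- make_gt(gene_id = c("g1", "g2", "g3"), k_control = 1e-12, c0 = c(10, 20, 30))
  gt$k_control <- gt$k_patient <- rep(0, 3)  # frozen transcriptome
  gt$baseline_attomole_patient <- gt$baseline_attomole
  dm <- simulate_decay_timecourse(gt, p, noiseless = TRUE)
  ctrl <- which(dm$samples$condition == "control")
  for (g in c("g1", "SPIKE-002")) {
    expect_equal(diff(range(dm$counts[g, ctrl])), 0)
  }
})

test_that("RIP enrichment equals 1 + reader_gain * m for bound targets", {
  p <- simulation_params(n_genes = 2, n_spikes = 3, dispersion = 0,
                         depth_cv = 0, depth_mean = 2e6, seed = 6)
  gt <- make_gt(gene_id = c("target", "bystander"), m = c(1, 0),
                c0 = c(50, 50), target = c(TRUE, FALSE))
  rip <- simulate_rip_counts(gt, p)
  cpm <- cpm_normalize(rip)
  fold <- function(g) mean(cpm[g, rip$samples$assay == "RIP"]) /
    mean(cpm[g, rip$samples$assay == "input"])
  # relative enrichment of the m = 1 target over the unbound gene is 7x
  expect_equal(fold("target") / fold("bystander"), 1 + p$reader_gain,
               tolerance = 0.02)

  # no reader targets -> no expected enrichment anywhere
  gt0 <- make_gt(gene_id = c("a", "b"), m = c(0.8, 0.2), c0 = c(50, 50),
                 target = FALSE)
  rip0 <- simulate_rip_counts(gt0, p)
  cpm0 <- cpm_normalize(rip0)
  lr <- log2(rowMeans(cpm0[, rip0$samples$assay == "RIP"]) /
               rowMeans(cpm0[, rip0$samples$assay == "input"]))
  expect_equal(unname(lr), c(0, 0), tolerance = 0.02)
})

test_that("proteomics generator honours missingness and the null", {
  p <- simulation_params(seed = 5)
  sim <- simulate_proteomics(p, n_proteins = 100, missing_rate = 0)
  expect_false(anyNA(sim$abundance))
  expect_identical(sim$abundance,
                   simulate_proteomics(p, n_proteins = 100, missing_rate = 0)$abundance)
  sim2 <- simulate_proteomics(p, n_proteins = 200, missing_rate = 0.2)
  expect_gt(mean(is.na(sim2$abundance)), 0.1)
  # zero down-shift: group means equal in expectation
  sim0 <- simulate_proteomics(p, n_proteins = 400, missing_rate = 0,
                              downshift_log2 = 0)
  d <- rowMeans(log2(sim0$abundance[, sim0$groups == "patient"])) -
    rowMeans(log2(sim0$abundance[, sim0$groups == "control"]))
  expect_lt(abs(mean(d)), 0.05)
})
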