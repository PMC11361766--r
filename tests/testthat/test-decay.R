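test_that("spike calibration recovers exact log-log relations", {
  # CPM = 10 x attomole: log10(amount) = log10(CPM) - 1
  counts <- matrix(c(1, 2, 3, 4) * 1e5, ncol = 1,
                   dimnames = list(sprintf("SPIKE-%03d", 1:4), "s1"))
  cm <- make_cm(counts, feature_kind = "spikein")
  ref <- data.frame(spike_id = rownames(counts),
                    amount_attomole = c(1, 2, 3, 4) * 1e4)
  fit <- fit_spikein_calibration(cm, ref)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_spikes_used, 4L)
  # CPM = attomole^2 is a log-log power law with exponent 1/2
  ref2 <- data.frame(spike_id = rownames(counts),
                     amount_attomole = sqrt(c(1, 2, 3, 4) * 1e5))
  fit2 <- fit_spikein_calibration(cm, ref2)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  # too few detected spikes is a named error
  counts0 <- counts; counts0[1:2, 1] <- 0
  expect_error(fit_spikein_calibration(make_cm(counts0, feature_kind = "spikein"), ref),
               "s1")
})

test_that("calibration agrees with closed-form OLS under perturbation", {
  set.seed(21)
  counts <- matrix(rpois(8, 10^(2:9 / 1.5)), ncol = 1,
                   dimnames = list(sprintf("SPIKE-%03d", 1:8), "s1"))
  ref <- data.frame(spike_id = rownames(counts),
                    amount_attomole = 10^seq(-1, 2, length.out = 8))
  counts[3, 1] <- counts[3, 1] + 25   # perturb one spike
  cm <- make_cm(counts, feature_kind = "spikein")
  fit <- fit_spikein_calibration(cm, ref)
  cpm <- cpm_normalize(cm)[, 1]
  lmfit <- lm(log10(ref$amount_attomole) ~ log10(cpm))
  expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
})

test_that("CPM converts to attomole through the fitted line", {
  fit <- list(slope = 1, intercept = -1)
  expect_equal(cpm_to_attomole(1000, fit), 100)
  expect_equal(cpm_to_attomole(c(10, 100), list(slope = 1, intercept = 0)),
               c(10, 100))
  expect_true(is.na(cpm_to_attomole(0, fit)))   # undetected -> censored
  x <- cpm_to_attomole(c(1, 10, 100), fit)
  expect_true(all(diff(x) > 0))                  # monotone for slope > 0
})

test_that("decay rate estimation is exact on exponentials and flags the rest", {
  expect_equal(estimate_kdecay(c(100, 50, 25), c(0, 3, 6)), log(2) / 3,
               tolerance = 1e-12)
  expect_equal(estimate_kdecay(c(100, 100, 100), c(0, 3, 6)), 0)
  expect_lt(estimate_kdecay(c(100, 120, 140), c(0, 3, 6)), 0)
  expect_true(is.na(estimate_kdecay(c(0, 50, 25), c(0, 3, 6))))
  expect_equal(half_life(0.0693147), 10, tolerance = 1e-4)
  expect_equal(half_life(log(2) / 3), 3)
  expect_true(is.na(half_life(0)))
  expect_true(is.na(half_life(-0.1)))
})

test_that("full decay pipeline recovers truth without noise", {
  p <- simulation_params(n_genes = 3, n_spikes = 8, depth_cv = 0, seed = 2)
  gt <- make_gt(gene_id = c("fast", "mid", "slow"),
                k_control = c(0.4, 0.2, 0.05), c0 = c(100, 60, 20))
  dm <- simulate_decay_timecourse(gt, p, noiseless = TRUE)
  hl <- estimate_decay(dm, spikein_reference(p), analysis_config())
  ctrl <- hl[hl$condition == "control", ]
  expect_equal(ctrl$c0_attomole, gt$baseline_attomole, tolerance = 1e-9)
  expect_equal(ctrl$k_per_h, gt$k_control, tolerance = 1e-10)
  # larger K means shorter half-life
  expect_true(all(diff(ctrl$halflife_h[order(ctrl$k_per_h)]) < 0))
  # averaging per-timepoint half-lives instead is identical on exact data
  hl2 <- estimate_decay(dm, spikein_reference(p),
                        analysis_config(halflife_average = "halflife"))
  expect_equal(hl2$halflife_h, hl$halflife_h, tolerance = 1e-10)
})

test_that("attomole estimates are invariant to rescaling one sample", {
  p <- simulation_params(n_genes = 5, n_spikes = 8, seed = 12)
  gt <- make_gt(gene_id = sprintf("g%d", 1:5), k_control = 0.2,
                c0 = c(5, 20, 50, 100, 200))
  dm <- simulate_decay_timecourse(gt, p)
  hl1 <- estimate_decay(dm, spikein_reference(p), analysis_config())
  dm$counts[, 1] <- dm$counts[, 1] * 3L   # triple one library's depth
  hl2 <- estimate_decay(dm, spikein_reference(p), analysis_config())
  expect_equal(hl2$halflife_h, hl1$halflife_h, tolerance = 1e-12)
})

test_that("half-life group comparison excludes censored values", {
  expect_equal(compare_half_life_groups(c(1, 2), c(3, 4))$p_value, 1 / 3)
  same <- compare_half_life_groups(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p_value, 1)
  expect_equal(same$delta_median, 0)
  r <- compare_half_life_groups(c(1, 2, NA, NA), c(3, 4, NA))
  expect_equal(r$n, c(2L, 2L))
  expect_equal(r$n_censored, c(2L, 1L))
  expect_error(compare_half_life_groups(c(1, NA), c(2, 3)), "uncensored")
})
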