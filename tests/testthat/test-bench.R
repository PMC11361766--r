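test_that("standard curves fit and degrade as specified", {
  conc <- c(1, 2, 5, 10)
  curve <- fit_standard_curve(conc, 2 * conc)
  expect_equal(curve$slope, 2)
  expect_equal(curve$intercept, 0)
  expect_equal(curve$r_squared, 1)
  # adding an exactly collinear point leaves the slope unchanged
  curve2 <- fit_standard_curve(c(conc, 20), c(2 * conc, 40))
  expect_equal(curve2$slope, 2)
  # flat signal: slope 0 and r^2 0, still a defined fit
  flat <- fit_standard_curve(conc, rep(3, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fit_standard_curve(c(1, 1, 2), c(1, 2, 3)), "3 distinct")
})

test_that("m6A/A ratio inverts both curves", {
  ident <- fit_standard_curve(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m6a_ratio(0.5, 100, ident, ident), 0.005)
  # common rescaling of both channels cancels for curves through the origin
  expect_equal(m6a_ratio(1, 200, ident, ident),
               m6a_ratio(2, 400, ident, ident))
  # closed loop: a known mixture measured through noiseless curves
  cm6a <- fit_standard_curve(c(1, 2, 4), 3 * c(1, 2, 4))
  ca <- fit_standard_curve(c(10, 20, 40), 0.7 * c(10, 20, 40))
  r <- 0.012; conc_a <- 50
  expect_equal(m6a_ratio(3 * (r * conc_a), 0.7 * conc_a, cm6a, ca), r)
  expect_error(m6a_ratio(0.1, 100, fit_standard_curve(c(1, 2, 3), c(5, 6, 7)), ident),
               "non-positive")
})

test_that("proteomic screen z-scores, filters and tests", {
  mat <- rbind(
    p0 = c(1, 2, 3, NA, NA, NA),        # z over the 3 available values
    p1 = c(1, 2, 3, 1, 2, 3),
    p2 = c(5, 5, NA, NA, NA, NA),       # missing in 4 -> kept at max_missing 4
    p3 = c(NA, NA, NA, NA, NA, 2),      # missing in 5 -> removed
    p4 = c(7, 7, 7, 7, 7, 7)            # zero variance -> flagged
  )
  colnames(mat) <- sprintf("s%d", 1:6)
  groups <- rep(c("control", "patient"), each = 3)
  out <- proteomics_screen(mat, groups, max_missing = 4)
  expect_equal(out$removed, "p3")
  expect_equal(unname(out$z["p0", 1:3]), c(-1, 0, 1))
  # z-scores have mean 0 and sample sd 1 over available values
  expect_equal(mean(out$z["p1", ]), 0)
  expect_equal(sd(out$z["p1", ]), 1)
  expect_true(out$test$zero_variance[out$test$protein_id == "p4"])
  expect_true(is.na(out$test$p[out$test$protein_id == "p4"]))
  # identical group distributions: exact p = 1
  expect_equal(out$test$p[out$test$protein_id == "p1"], 1)
})

test_that("batch normalization divides by the batch control sample", {
  mat <- rbind(p1 = c(2, 4, 10, 30), p2 = c(1, 3, 5, 5))
  colnames(mat) <- c("b1c", "b1x", "b2c", "b2x")
  out <- proteomics_screen(mat, groups = c("control", "patient", "control", "patient"),
                           max_missing = 0,
                           batch = c("b1", "b1", "b2", "b2"),
                           batch_control = c(b1 = "b1c", b2 = "b2c"))
  # after normalization p1 is (1, 2, 1, 3): z-scores reflect those ratios
  expect_equal(unname(out$z["p1", ]),
               unname((c(1, 2, 1, 3) - mean(c(1, 2, 1, 3))) / sd(c(1, 2, 1, 3))))
})

test_that("screen separates a down-shifted protein set", {
  sim <- simulate_proteomics(simulation_params(seed = 8), n_proteins = 200,
                             missing_rate = 0.05, downshift_log2 = 2)
  out <- proteomics_screen(sim$abundance, sim$groups, max_missing = 4)
  hit <- out$test$padj < 0.05 & !is.na(out$test$padj)
  truth <- sim$is_downshifted[as.integer(sub("prot_", "", out$test$protein_id))]
  expect_gt(mean(hit[truth]), 0.7)
  expect_lt(mean(hit[!truth]), 0.05)
})
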