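test_that("the default design encodes the study conditions", {
  d <- default_design()
  expect_equal(d$cells_per_sample, 100)
  expect_equal(d$dose_range, c(6, 95))
  expect_equal(d$slope_mean, 0.0150)
  expect_equal(d$slope_sd, 0.0018)
  expect_equal(d$n_samples, 55)
  expect_equal(d$n_subjects, 3)
  expect_equal(d$induced_intercept, 0.0363)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_study(default_design(), seed = 7)
  b <- generate_study(default_design(), seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_study(default_design(), seed = 8)
  expect_false(identical(a$samples$total_foci, c$samples$total_foci))
})

test_that("generated tables have the declared structure", {
  s <- generate_study(default_design(), seed = 3)$samples
  expect_equal(nrow(s), 55)
  expect_equal(length(unique(s$dataset_id)), 9)
  expect_equal(length(unique(s$subject_id)), 3)
  expect_setequal(unique(s$nuclide), c("I-131", "Lu-177"))
  expect_true(all(s$total_foci >= 0 & s$total_foci == round(s$total_foci)))
  expect_true(all(s$dose_mGy >= 6 & s$dose_mGy <= 95))
  expect_true(all(s$true_background >= 0.10 & s$true_background <= 0.25))
  # one shared background aliquot per dataset
  bg <- tapply(s$bg_total_foci, s$dataset_id, function(v)
    length(unique(v)))
  expect_true(all(bg == 1))
})

test_that("per-sample means converge to the generating line at large cell counts", {
  d <- default_design()
  d$cells_per_sample <- 1e7
  d$slope_sd <- 0
  d$induced_intercept <- 0
  d$background_mean <- 0; d$background_sd <- 0; d$background_range <- c(0, 0)
  s <- generate_study(d, seed = 13)$samples
  net <- s$total_foci / s$cells_scored - s$bg_total_foci / s$bg_cells_scored
  expect_equal(net, d$slope_mean * s$dose_mGy, tolerance = 2e-3)
})

test_that("net RIF spans roughly the published range", {
  for (seed in 1:4) {
    s <- generate_study(default_design(), seed = seed)$samples
    net <- s$total_foci / s$cells_scored - s$bg_total_foci / s$bg_cells_scored
    expect_gt(max(net), 1.1)
    expect_lt(min(net), 0.35)
    expect_true(all(net > -0.3 & net < 2.1))
  }
})

test_that("net RIF increases with dose in every replicate", {
  set.seed(23)
  for (i in 1:20) {
    s <- generate_study(default_design(), seed = NULL)$samples
    net <- s$total_foci / s$cells_scored - s$bg_total_foci / s$bg_cells_scored
    expect_gt(cor(s$dose_mGy, net, method = "spearman"), 0)
  }
})

test_that("foci totals are Poisson: variance tracks the mean", {
  d <- default_design()
  d$n_subjects <- 1; d$draws_per_subject <- 1; d$n_samples <- 400
  d$dose_range <- c(50, 50 + 1e-9); d$slope_sd <- 0
  d$background_sd <- 0; d$background_range <- c(0.17, 0.17)
  s <- generate_study(d, seed = 17)$samples
  ratio <- var(s$total_foci) / mean(s$total_foci)
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
})

test_that("noise-free generation recovers the slope exactly", {
  d <- default_design()
  d$slope_sd <- 0; d$poisson <- FALSE
  rec <- replicate_study(d, 3, seed = 29)
  expect_equal(rec$slopes_mean, rep(d$slope_mean, 3), tolerance = 1e-9)
  expect_equal(rec$pooled_r2, rep(1, 3), tolerance = 1e-6)
})

test_that("pathological designs are refused", {
  d <- default_design()
  d$induced_intercept <- -5
  expect_error(generate_study(d, seed = 1), "pathological|negative")
})

test_that("slope recovery is unbiased within Monte Carlo error", {
  rec <- replicate_study(default_design(), 50, seed = 37)
  mc_se <- sd(rec$slopes_mean) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$slopes_mean) - 0.0150), 3 * mc_se + 1e-4)
})
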