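test_that("two-site occupancy reproduces the 150/300 fmol worked example", {
  occ <- two_site_double_occupancy(150, 300)
  expect_equal(occ$fraction, 0.25)
  expect_equal(occ$amount_fully_occupied, 37.5)
  expect_equal(occ$n_molecules, 150)
  zero <- two_site_double_occupancy(0, 300)
  expect_equal(zero$fraction, 0)
  expect_equal(zero$amount_fully_occupied, 0)
  expect_error(two_site_double_occupancy(301, 300), "more SHs")
})

test_that("exact placement matches enumeration and converges to independence", {
  # 2 SHs on 4 sites (2 molecules): enumerate all C(4,2) placements
  placements <- utils::combn(4, 2)
  molecule_of <- c(1, 1, 2, 2)
  frac_enum <- mean(apply(placements, 2, function(occ) {
    full <- vapply(1:2, function(m) all(which(molecule_of == m) %in% occ),
                   logical(1))
    mean(full)
  }))
  occ <- two_site_double_occupancy(2, 4, mode = "exact_placement")
  expect_equal(occ$fraction, frac_enum) # 1/6
  expect_equal(occ$fraction, 1 / 6)
  # convergence to the independent-site approximation at fixed occupancy
  for (ratio in c(0.25, 0.5, 0.75)) {
    gap_small <- abs(
      two_site_double_occupancy(ratio * 40, 40, mode = "exact_placement")$fraction -
        ratio^2)
    gap_big <- abs(
      two_site_double_occupancy(ratio * 4000, 4000,
                                mode = "exact_placement")$fraction - ratio^2)
    expect_lt(gap_big, gap_small)
    expect_lt(gap_big, 1e-3)
  }
})

test_that("predicted maximum yield is the product of its factors", {
  expect_equal(predicted_max_yield(150, 0.25, 0.5), 18.75)
  expect_lt(predicted_max_yield(150, 0.25, 0.5), 20) # "less than 20 fmol"
  expect_equal(predicted_max_yield(150, 0.25, 1), 37.5)
  expect_equal(predicted_max_yield(0, 0.25, 0.5), 0)
  expect_equal(predicted_max_yield(150, 0, 0.5), 0)
})

test_that("half-life fit inverts a noiseless exponential exactly", {
  tc <- gen_retention_timecourse(3.5, times = c(0, 2, 4, 8, 16),
                                 noise_cv = 0, seed = 1)
  fit <- fit_half_life(tc$time, tc$signal, n_boot = 200, seed = 2)
  expect_equal(fit$estimate, 3.5, tolerance = 1e-6)
  expect_false(fit$warning_flag)
  expect_true(fit$ci95[1] <= fit$estimate && fit$estimate <= fit$ci95[2])
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
})

test_that("noisy retention series recover the generating half-life", {
  tc <- gen_retention_timecourse(3.5, noise_cv = 0.05, seed = 42)
  fit <- fit_half_life(tc$time, tc$signal, n_boot = 1000, seed = 43)
  expect_true(fit$ci95[1] <= 3.5 && 3.5 <= fit$ci95[2])
  expect_equal(fit$estimate, 3.5, tolerance = 0.15)
})

test_that("half-life estimator is unbiased at generator default noise", {
  ests <- vapply(1:200, function(r) {
    tc <- gen_retention_timecourse(3.5, noise_cv = 0.05, seed = 1000 + r)
    fit_half_life(tc$time, tc$signal, n_boot = 0)$estimate
  }, numeric(1))
  expect_equal(mean(ests), 3.5, tolerance = 0.02 * 3.5)
})

test_that("non-decaying retention data are flagged with an infinite sentinel", {
  expect_warning(
    fit <- fit_half_life(c(0, 2, 4, 8), rep(50, 4), n_boot = 0),
    "does not decay")
  expect_true(fit$warning_flag)
  expect_identical(fit$estimate, Inf)
})

test_that("MSD regression recovers trivial and diffusive tracks", {
  flat <- estimate_diffusion_coefficient(rep(3.2, 200), dt = 1e-3)
  expect_equal(flat$estimate, 0)
  x <- gen_tracking_trajectory(800, 1e-3, 1e5, seed = 7)
  fit <- estimate_diffusion_coefficient(x, 1e-3)
  expect_equal(fit$estimate, 800, tolerance = 0.05 * 800)
  expect_true(fit$ci95[1] <= 800 && 800 <= fit$ci95[2])
  expect_false(fit$warning_flag)
  expect_error(estimate_diffusion_coefficient(1:5, 1e-3, max_lag = 10),
               "track length")
})

test_that("drift tracks are flagged for superlinear MSD growth", {
  drift <- (0:2000) * 1e-3 * 50 # pure linear motion: MSD quadratic in lag
  expect_warning(fit <- estimate_diffusion_coefficient(drift, 1e-3),
                 "not linear")
  expect_true(fit$warning_flag)
})

test_that("block confidence intervals cover the true D at nominal rate", {
  hits <- vapply(1:100, function(r) {
    x <- gen_tracking_trajectory(800, 1e-3, 1e4, seed = 2000 + r)
    ci <- estimate_diffusion_coefficient(x, 1e-3)$ci95
    ci[1] <= 800 && 800 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("ddCt fold changes behave like ratios of ratios", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  # target amplifies one cycle earlier under induction: twofold enrichment
  expect_equal(ddct_fold_change(19, 20, 20, 20), 2)
  f <- ddct_fold_change(21.3, 18.2, 24.9, 19.1)
  f_swapped <- ddct_fold_change(24.9, 19.1, 21.3, 18.2)
  expect_equal(f_swapped, 1 / f)
  expect_error(ddct_fold_change(Inf, 20, 20, 20))
})
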