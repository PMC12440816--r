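test_that("per-step dissociation probability matches its two definitions", {
  # memoryless: half the SHs gone after one half-life-sized step
  expect_equal(dissociation_probability(180, 180), 0.5)
  expect_equal(dissociation_probability(1, Inf), 0)
  # literal density rule at t = 0 equals 1/tau = ln2 / half_life
  expect_equal(dissociation_probability(1e-5, 180, t = 0, mode = "as_printed"),
               log(2) / 180, tolerance = 1e-12)
  expect_equal(log(2) / 180, 3.85e-3, tolerance = 1e-3)
  # memoryless survival over k steps is exactly 2^(-k dt / half_life)
  p <- dissociation_probability(0.1, 180)
  expect_equal((1 - p)^1800, 0.5, tolerance = 1e-12)
})

test_that("step displacements are mean-zero Gaussian with variance 2 D dt", {
  expect_identical(step_displacement(0, 1e-5, 100), rep(0, 100))
  set.seed(101)
  n <- 1e6
  d <- step_displacement(800, 1e-5, n)
  v <- 2 * 800 * 1e-5 # 0.016 bp^2
  expect_lt(abs(mean(d)), 3 * sqrt(v / n))
  expect_lt(abs(var(d) - v), 3 * v * sqrt(2 / n))
})

test_that("trajectories with zero initial gap collide immediately", {
  for (s in c(1L, 99L)) {
    tr <- simulate_trajectory(82, coarse_params(), seed = s)
    expect_identical(tr$fate, "collision")
    expect_identical(tr$event_time, 0)
  }
  est <- dh_formation_efficiency(82, coarse_params(), 200, seed = 4)
  expect_identical(est$p_dh, 1)
})

test_that("frozen immortal hexamers always time out", {
  p <- diffusion_params(D = 0, dt = 1e-3, half_life = Inf, total_time = 2)
  for (s in 1:3) {
    tr <- simulate_trajectory(300, p, seed = s)
    expect_identical(tr$fate, "timeout")
    expect_identical(tr$event_time, 2)
  }
})

test_that("stepping engine matches the first-passage oracle at 90 bp", {
  p <- coarse_params()
  est <- dh_formation_efficiency(90, p, n_trajectories = 2000, seed = 42)
  p_oracle <- collision_probability(relative_process_from(90, p))
  expect_equal(p_oracle, 0.98, tolerance = 0.005) # the expected ~98%
  expect_lt(abs(est$p_dh - p_oracle), 3 * est$mc_se)
})

test_that("engine runs are bit-for-bit reproducible under a fixed seed", {
  p <- coarse_params(total_time = 60, half_life = 60)
  a <- dh_formation_efficiency(120, p, 300, seed = 7)
  b <- dh_formation_efficiency(120, p, 300, seed = 7)
  expect_identical(a$p_dh, b$p_dh)
  expect_identical(a$collision_times, b$collision_times)
  c_ <- dh_formation_efficiency(120, p, 300, seed = 8)
  expect_false(identical(a$collision_times, c_$collision_times))
  # engine RNG is independent of R's RNG state
  set.seed(1); d <- dh_formation_efficiency(120, p, 300, seed = 7)
  expect_identical(a$collision_times, d$collision_times)
})

test_that("SH survival is exponential with the configured half-life", {
  lt <- sample_sh_lifetimes(5000, dt = 0.1, half_life = 180, seed = 11)
  for (t in c(30, 60, 120, 180, 360)) {
    expected <- 2^(-t / 180)
    se <- sqrt(expected * (1 - expected) / 5000)
    expect_lt(abs(mean(lt > t) - expected), 3 * se)
  }
})

test_that("the literal density hazard is not exponential at fine steps", {
  # at dt = 1 ms the printed rule kills essentially every SH within a second
  lt <- sample_sh_lifetimes(200, dt = 1e-3, half_life = 180, max_time = 5,
                            seed = 3, mode = "as_printed")
  expect_true(all(is.finite(lt)))
  expect_lt(median(lt), 1)
})

test_that("empirical collision-time CDF is monotone and ends at p_dh", {
  p <- coarse_params(total_time = 60, half_life = 60)
  est <- dh_formation_efficiency(120, p, 500, seed = 9)
  ts <- seq(0, 60, length.out = 50)
  cdf <- est$cdf(ts)
  expect_true(all(diff(cdf) >= 0))
  expect_equal(est$cdf(p$total_time), est$p_dh)
  expect_equal(cdf[1], 0)
})

test_that("separation sweep normalizes to its maximum and flags bad input", {
  p <- coarse_params()
  sw <- sweep_separations(c(82, 90, 150, 300), p, n_trajectories = 5000,
                          seed = 2, engine = "fast")
  expect_named(sw, c("separation_bp", "p_dh", "mc_se", "relative_efficiency",
                     "n_collision", "n_dissociation", "n_timeout"))
  expect_equal(sw$separation_bp[which.max(sw$p_dh)], 82)
  expect_equal(max(sw$relative_efficiency), 1)
  expect_true(all(diff(sw$p_dh) <= 0)) # wide gaps: monotone even with MC noise
  expect_equal(sw$n_collision + sw$n_dissociation + sw$n_timeout,
               rep(5000L, 4))

  one <- sweep_separations(150, p, 2000, seed = 3, engine = "fast")
  expect_equal(one$relative_efficiency, 1)

  expect_error(sweep_separations(c(90, 50), p, 10, seed = 1), "50")
})

test_that("stepping sweep is ordered like the oracle at short horizon", {
  p <- coarse_params(total_time = 60, half_life = 60)
  sw <- sweep_separations(c(82, 90, 120), p, n_trajectories = 400, seed = 5)
  expect_equal(sw$p_dh[1], 1)
  expect_gt(sw$p_dh[2], sw$p_dh[3])
})

test_that("reflecting template ends raise the meeting probability", {
  p <- coarse_params(total_time = 120)
  refl_geom <- template_geometry(300, template_length = 400,
                                 boundary_mode = "reflecting")
  p_refl <- dh_formation_efficiency(300, p, 400, seed = 21,
                                    geometry = refl_geom)$p_dh
  p_free <- dh_formation_efficiency(300, p, 400, seed = 21)$p_dh
  expect_gt(p_refl, p_free)
})
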