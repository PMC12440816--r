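#' Kinetic parameters of the SH diffusion model
#'
#' Bundles the kinetic constants of the stochastic model: the SH
#' one-dimensional diffusion coefficient on DNA (800 bp^2/s from
#' single-molecule tracking), the simulation time step, the SH dissociation
#' half-life on DNA, and the simulated horizon matching the 20-minute bulk
#' incubation.
#'
#' Two half-life presets are in circulation for the same retention assay:
#' 3 min (the value the simulation methods quote) and approximately 3.5 min
#' (the value quoted alongside the retention figure); see
#' [sh_half_life_presets].
#'
#' The dissociation hazard has two modes. `"memoryless"` (default) applies
#' the exact per-step probability `1 - 2^(-dt / half_life)`, which yields
#' exponential survival with the stated half-life at any step size.
#' `"as_printed"` applies the exponential *density* `(1/tau) exp(-t/tau)`
#' (tau = half_life / ln 2) directly as a per-step probability, clipped to
#' [0, 1]; this rule is not a probability (it lacks a dt factor), is retained
#' only for auditing, and at small dt kills every SH within milliseconds.
#'
#' @param D Diffusion coefficient in bp^2/s (default 800).
#' @param dt Time step in s (default 1e-5).
#' @param half_life SH dissociation half-life in s (default 180).
#' @param total_time Simulated horizon in s (default 1200).
#' @param hazard_mode `"memoryless"` or `"as_printed"`.
#' @return An object of class `diffusion_params`; includes the derived mean
#'   lifetime `tau = half_life / ln 2`.
#' @examples
#' diffusion_params()$tau # 259.7 s
#' @export
diffusion_params <- function(D = 800, dt = 1e-5, half_life = 180,
                             total_time = 1200,
                             hazard_mode = c("memoryless", "as_printed")) {
  hazard_mode <- match.arg(hazard_mode)
  stopifnot(D >= 0, dt > 0, half_life > 0, total_time > 0)
  structure(
    list(D = D, dt = dt, half_life = half_life, total_time = total_time,
         hazard_mode = hazard_mode, tau = half_life / log(2)),
    class = "diffusion_params"
  )
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("SH diffusion parameters\n")
  cat("  D:          ", x$D, "bp^2/s\n")
  cat("  dt:         ", x$dt, "s\n")
  cat("  half-life:  ", x$half_life, "s (tau =", signif(x$tau, 5), "s)\n")
  cat("  horizon:    ", x$total_time, "s\n")
  cat("  hazard:     ", x$hazard_mode, "\n")
  invisible(x)
}

#' Named SH half-life presets (seconds)
#'
#' `methods_3min` is the half-life the simulation methods use;
#' `results_3p5min` is the "approximately 3.5 min" quoted for the same
#' retention time-course.
#' @format Named numeric vector of seconds.
#' @export
sh_half_life_presets <- c(methods_3min = 180, results_3p5min = 210)

#' Gaussian displacement draws for one time step
#'
#' Displacements of a freely diffusing SH over one step are i.i.d. normal
#' with mean 0 and variance `2 * D * dt` (the one-dimensional MSD).
#'
#' @param D Diffusion coefficient in bp^2/s.
#' @param dt Time step in s.
#' @param n Number of draws.
#' @return Numeric vector of displacements in bp (uses R's RNG).
#' @export
step_displacement <- function(D, dt, n) {
  stopifnot(D >= 0, dt > 0, n >= 0)
  stats::rnorm(n, mean = 0, sd = sqrt(2 * D * dt))
}

#' Per-step SH dissociation probability
#'
#' In `"memoryless"` mode returns `1 - 2^(-dt / half_life)`, the exact
#' per-step hazard whose survival curve is exponential with the stated
#' half-life. In `"as_printed"` mode returns the exponential lifetime
#' density `(1/tau) exp(-t/tau)` evaluated at elapsed time `t` and clipped
#' to [0, 1]; note this form is a density (units 1/s), not a probability,
#' and is provided only so the literal rule can be audited.
#'
#' @param dt Time step in s.
#' @param half_life Half-life in s (may be `Inf`).
#' @param t Elapsed time since loading in s (used by `as_printed` only).
#' @param mode `"memoryless"` or `"as_printed"`.
#' @return Probability in [0, 1].
#' @examples
#' dissociation_probability(180, 180) # 0.5
#' @export
dissociation_probability <- function(dt, half_life, t = 0,
                                     mode = c("memoryless", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, half_life > 0, all(t >= 0))
  if (is.infinite(half_life)) return(0)
  if (mode == "memoryless") {
    1 - 2^(-dt / half_life)
  } else {
    tau <- half_life / log(2)
    pmin(1, exp(-t / tau) / tau)
  }
}

fate_levels <- c("collision", "dissociation", "timeout")

#' Simulate one pair of diffusing SHs until collision, dissociation or timeout
#'
#' Initializes two SHs at the loading positions of `geometry` (N-termini
#' facing, gap = `initial_gap`). Each time step both SHs take independent
#' Gaussian displacements with variance `2 D dt`; the gap is tested at the
#' end of the full step and the first step with gap <= 0 is the collision
#' (DH formation) event, whose time is the first-passage time. Each
#' surviving SH then dissociates with [dissociation_probability()]; if
#' either SH dissociates the trajectory ends (DH formation is no longer
#' possible). Reflecting boundary mode folds N-terminus positions back at
#' the template ends.
#'
#' @param separation Separation in bp between the ORC site 5' ends, or a
#'   [template_geometry()] (overriding `geometry`).
#' @param params A [diffusion_params()] object.
#' @param seed Integer seed; the engine uses its own counter-based RNG, so
#'   results do not depend on R's RNG state.
#' @param geometry A [template_geometry()]; built from `separation` with
#'   default footprints when omitted.
#' @return A list with `fate` (one of `"collision"`, `"dissociation"`,
#'   `"timeout"`) and `event_time` in s.
#' @export
simulate_trajectory <- function(separation, params = diffusion_params(),
                                seed = 1L, geometry = NULL) {
  res <- simulate_batch(separation, params, n_trajectories = 1L, seed = seed,
                        geometry = geometry)
  list(fate = fate_levels[res$fate[1]], event_time = res$time[1])
}

# Shared driver: n trajectories through the C++ stepping core.
simulate_batch <- function(separation, params, n_trajectories, seed,
                           geometry = NULL) {
  if (inherits(separation, "template_geometry")) {
    geometry <- separation
  } else if (is.null(geometry)) {
    geometry <- template_geometry(separation)
  } else if (geometry$separation != separation) {
    geometry <- template_geometry(separation, geometry$orc_overhang,
                                  geometry$sh_footprint,
                                  geometry$template_length,
                                  geometry$boundary_mode)
  }
  stopifnot(inherits(params, "diffusion_params"), n_trajectories >= 1)
  cpp_simulate_batch(
    geometry$x1_0, geometry$x2_0, params$D, params$dt, params$half_life,
    params$total_time, as.integer(n_trajectories), as.double(seed),
    params$hazard_mode == "memoryless",
    geometry$boundary_mode == "reflecting",
    geometry$t_lo, geometry$t_hi
  )
}

#' Monte-Carlo estimate of DH-formation efficiency at one separation
#'
#' Runs `n_trajectories` seeded independent trajectories
#' ([simulate_trajectory()]) and aggregates: `p_dh` is the collision
#' fraction, `mc_se` its binomial standard error, and `cdf` the empirical
#' cumulative collision-time distribution C(t) (non-collisions contribute no
#' mass, so C(total_time) = p_dh) -- the probability that DH formation has
#' occurred by time t.
#'
#' @inheritParams simulate_trajectory
#' @param n_trajectories Number of trajectories.
#' @return An object of class `dh_efficiency`: `p_dh`, `mc_se`,
#'   `n_trajectories`, fate counts, collision times, and `cdf` (a function
#'   of t in s).
#' @export
dh_formation_efficiency <- function(separation, params = diffusion_params(),
                                    n_trajectories = 1000L, seed = 1L,
                                    geometry = NULL) {
  res <- simulate_batch(separation, params, n_trajectories, seed, geometry)
  new_dh_efficiency(res$fate, res$time, params$total_time)
}

# Common EfficiencyEstimate constructor used by both engines.
new_dh_efficiency <- function(fate, time, total_time) {
  n <- length(fate)
  coll <- fate == 1L
  p <- mean(coll)
  t_coll <- sort(time[coll])
  structure(
    list(
      p_dh = p,
      mc_se = sqrt(p * (1 - p) / n),
      n_trajectories = n,
      n_collision = sum(coll),
      n_dissociation = sum(fate == 2L),
      n_timeout = sum(fate == 3L),
      collision_times = t_coll,
      total_time = total_time,
      cdf = function(t) {
        stopifnot(all(t >= 0))
        vapply(t, function(ti) sum(t_coll <= ti), numeric(1)) / n
      }
    ),
    class = "dh_efficiency"
  )
}

#' @export
print.dh_efficiency <- function(x, ...) {
  cat("DH-formation efficiency estimate\n")
  cat(sprintf("  p_DH = %.4f (MC s.e. %.4f, n = %d)\n",
              x$p_dh, x$mc_se, x$n_trajectories))
  cat(sprintf("  fates: %d collision / %d dissociation / %d timeout\n",
              x$n_collision, x$n_dissociation, x$n_timeout))
  invisible(x)
}

#' Efficiency curve over a grid of ORC-site separations
#'
#' Estimates DH-formation efficiency at each separation and normalizes the
#' curve to its maximum ("relative efficiency"). Reproducible given the
#' seed: separation i uses substream seed + i so the grid can be extended
#' without perturbing earlier rows.
#'
#' @param separations Numeric vector of separations in bp (all must be at
#'   least the loading minimum).
#' @param params A [diffusion_params()].
#' @param n_trajectories Trajectories per separation.
#' @param seed Integer seed.
#' @param engine `"stepping"` (the Gaussian-step engine) or `"fast"` (the
#'   exact first-passage sampler, [fast_outcome_sampler()]).
#' @param geometry Optional [template_geometry()] supplying footprint
#'   constants and boundary mode (its separation field is replaced per row).
#' @return A tibble with columns `separation_bp`, `p_dh`, `mc_se`,
#'   `relative_efficiency`, `n_collision`, `n_dissociation`, `n_timeout`.
#' @export
sweep_separations <- function(separations, params = diffusion_params(),
                              n_trajectories = 1000L, seed = 1L,
                              engine = c("stepping", "fast"),
                              geometry = NULL) {
  engine <- match.arg(engine)
  min_sep <- if (is.null(geometry)) closest_loading_separation()
             else closest_loading_separation(geometry)
  bad <- separations[separations < min_sep]
  if (length(bad) > 0) {
    stop("separation(s) below the ", min_sep, " bp loading minimum: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(separations), function(i) {
    est <- if (engine == "stepping") {
      dh_formation_efficiency(separations[i], params, n_trajectories,
                              seed = seed + i, geometry = geometry)
    } else {
      fast_outcome_sampler(separations[i], params, n_trajectories,
                           seed = seed + i, geometry = geometry)
    }
    tibble::tibble(
      separation_bp = separations[i],
      p_dh = est$p_dh,
      mc_se = est$mc_se,
      n_collision = est$n_collision,
      n_dissociation = est$n_dissociation,
      n_timeout = est$n_timeout
    )
  })
  out <- do.call(rbind, rows)
  out$relative_efficiency <- out$p_dh / max(out$p_dh)
  out[, c("separation_bp", "p_dh", "mc_se", "relative_efficiency",
          "n_collision", "n_dissociation", "n_timeout")]
}

#' Sample single-SH lifetimes under the per-step dissociation rule
#'
#' Draws `n` SH residence times on DNA with no collision partner: at each
#' step of size `dt` the SH dissociates with [dissociation_probability()].
#' Used for survival-curve checks and for measuring the median SH lifetime.
#'
#' @param n Number of lifetimes.
#' @param dt Step size in s.
#' @param half_life Half-life in s.
#' @param max_time Censoring horizon in s; survivors report `Inf`.
#' @param seed Integer seed (engine RNG, independent of R's).
#' @param mode Hazard mode as in [dissociation_probability()].
#' @return Numeric vector of lifetimes in s (`Inf` = survived past
#'   `max_time`).
#' @export
sample_sh_lifetimes <- function(n, dt = 0.1, half_life = 180,
                                max_time = 3600, seed = 1L,
                                mode = c("memoryless", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, dt > 0, half_life > 0, max_time > 0)
  cpp_sample_lifetimes(as.integer(n), dt, half_life, max_time,
                       as.double(seed), mode == "memoryless")
}
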