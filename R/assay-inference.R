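#' Fraction of two-site DNA molecules carrying two SHs
#'
#' Given `n_sh` single hexamers distributed at random over `n_sites` ORC
#' binding sites on molecules carrying `sites_per_molecule` sites each,
#' computes the expected fraction (and absolute amount) of molecules with
#' every site occupied -- the prerequisite for DH formation by SH collision.
#'
#' `independent` mode (the default, and the approximation behind the
#' published 150/300 fmol -> 25% worked example) treats each site as
#' occupied independently with probability `n_sh / n_sites`, so the doubly
#' occupied fraction is that probability squared. `exact_placement` places
#' the SHs on distinct sites uniformly at random, giving the hypergeometric
#' expectation `n_sh (n_sh - 1) / (n_sites (n_sites - 1))` for two-site
#' molecules (slightly below the independent value at finite counts,
#' converging to it as the system grows at fixed occupancy).
#'
#' @param n_sh Amount of loaded SHs (e.g. fmol).
#' @param n_sites Amount of ORC binding sites (same units); must be at least
#'   `n_sh` and divisible into molecules.
#' @param sites_per_molecule Sites per DNA molecule (default 2).
#' @param mode `"independent"` or `"exact_placement"`.
#' @return A list: `fraction` of molecules fully occupied,
#'   `amount_fully_occupied` in the input units, `n_molecules`.
#' @examples
#' two_site_double_occupancy(150, 300) # 25%, 37.5 fmol
#' @export
two_site_double_occupancy <- function(n_sh, n_sites, sites_per_molecule = 2,
                                      mode = c("independent",
                                               "exact_placement")) {
  mode <- match.arg(mode)
  stopifnot(n_sh >= 0, n_sites > 0, sites_per_molecule >= 1)
  if (n_sh > n_sites)
    stop("more SHs (", n_sh, ") than binding sites (", n_sites, ")",
         call. = FALSE)
  n_mol <- n_sites / sites_per_molecule
  frac <- if (mode == "independent") {
    (n_sh / n_sites)^sites_per_molecule
  } else {
    # P(all k sites of one molecule occupied) under uniform distinct placement
    k <- sites_per_molecule
    if (n_sh < k) 0 else prod((n_sh - seq_len(k) + 1) /
                              (n_sites - seq_len(k) + 1))
  }
  list(fraction = frac,
       amount_fully_occupied = frac * n_mol,
       n_molecules = n_mol)
}

#' Predicted maximum DH yield
#'
#' Combines the amount of DNA molecules, the fraction carrying two SHs, and
#' the collision (DH-formation) efficiency at the template's site
#' separation into an upper bound on the DH yield.
#'
#' @param n_molecules Amount of DNA molecules (e.g. fmol).
#' @param double_occupancy_fraction Fraction of molecules with two SHs.
#' @param collision_efficiency DH-formation probability given two SHs.
#' @return Predicted yield in the units of `n_molecules`.
#' @examples
#' predicted_max_yield(150, 0.25, 0.5) # 18.75 fmol, i.e. "less than 20"
#' @export
predicted_max_yield <- function(n_molecules, double_occupancy_fraction,
                                collision_efficiency) {
  stopifnot(n_molecules >= 0,
            double_occupancy_fraction >= 0, double_occupancy_fraction <= 1,
            collision_efficiency >= 0, collision_efficiency <= 1)
  n_molecules * double_occupancy_fraction * collision_efficiency
}

new_fit_result <- function(estimate, ci95, units, residual_sd,
                           warning_flag = FALSE, details = list()) {
  structure(
    c(list(estimate = estimate, ci95 = ci95, units = units,
           residual_sd = residual_sd, warning_flag = warning_flag),
      details),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit: %s %s (95%% CI %s - %s)%s\n",
              format(signif(x$estimate, 4)), x$units,
              format(signif(x$ci95[1], 4)), format(signif(x$ci95[2], 4)),
              if (isTRUE(x$warning_flag)) "  [flagged]" else ""))
  invisible(x)
}

#' Fit an exponential half-life to a retention time-course
#'
#' Fits `signal = A * 2^(-t / half_life)` by ordinary least squares on the
#' log2 scale (the log transform stabilizes the multiplicative noise typical
#' of bead-retention assays), so `half_life = -1 / slope`. A nonparametric
#' residual bootstrap (seeded) supplies the 95% percentile interval.
#'
#' Non-decaying data (slope >= 0) return a flagged result with an infinite
#' half-life sentinel.
#'
#' @param times Time points (strictly increasing; any unit).
#' @param signals Positive signals at those times.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (applied locally).
#' @return A `fit_result`: `estimate` (half-life, units of `times`),
#'   `ci95`, `residual_sd` (log2 scale), `warning_flag`, plus the fitted
#'   `amplitude`.
#' @examples
#' tc <- gen_retention_timecourse(3.5, times = c(0, 2, 4, 8, 16),
#'                                noise_cv = 0, seed = 1)
#' fit_half_life(tc$time, tc$signal)$estimate # 3.5 exactly
#' @export
fit_half_life <- function(times, signals, n_boot = 1000L, seed = 1L) {
  stopifnot(length(times) == length(signals), length(times) >= 3,
            all(diff(times) > 0))
  keep <- signals > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " non-positive signal(s) before log fit")
    times <- times[keep]
    signals <- signals[keep]
  }
  stopifnot(length(times) >= 3)
  y <- log2(signals)
  fit <- stats::lm(y ~ times)
  slope <- stats::coef(fit)[["times"]]
  amp <- 2^stats::coef(fit)[["(Intercept)"]]
  resid_sd <- stats::sd(stats::residuals(fit))
  if (slope >= 0) {
    warning("signal does not decay; returning infinite half-life sentinel")
    return(new_fit_result(Inf, c(Inf, Inf), units = "time units of input",
                          residual_sd = resid_sd, warning_flag = TRUE,
                          details = list(amplitude = amp)))
  }
  est <- -1 / slope
  fitted_y <- stats::fitted(fit)
  r <- stats::residuals(fit)
  boot <- numeric(0)
  if (n_boot > 0) {
    seed_locally(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      yb <- fitted_y + sample(r, length(r), replace = TRUE)
      sb <- stats::coef(stats::lm(yb ~ times))[["times"]]
      if (sb >= 0) NA_real_ else -1 / sb
    }, numeric(1))
    boot <- boot[is.finite(boot)]
  }
  ci <- if (length(boot) >= 10)
    stats::quantile(boot, c(0.025, 0.975), names = FALSE) else c(NA_real_, NA_real_)
  # percentile interval widened to contain the point estimate if bootstrap
  # skew pushed it outside
  if (!anyNA(ci)) ci <- range(c(ci, est))
  new_fit_result(est, ci, units = "time units of input",
                 residual_sd = resid_sd,
                 details = list(amplitude = amp, slope = slope))
}

#' Mean squared displacement of a 1D track
#'
#' `MSD(k) = mean over i of (x[i+k] - x[i])^2` using all (overlapping)
#' origins.
#'
#' @param positions Numeric positions (bp).
#' @param lags Integer lags (steps).
#' @return Numeric vector of MSDs (bp^2).
#' @export
track_msd <- function(positions, lags) {
  n <- length(positions)
  stopifnot(all(lags >= 1), all(lags < n))
  vapply(lags, function(k)
    mean((positions[(k + 1):n] - positions[1:(n - k)])^2), numeric(1))
}

#' Estimate a diffusion coefficient from a tracking trajectory
#'
#' Computes the MSD at lags `1..max_lag` and fits `MSD = 2 D (k dt)` by a
#' weighted (1/lag) linear regression through the origin; short lags carry
#' more weight because their MSD estimates average more displacement pairs
#' and have smaller relative variance. The 95% CI comes from re-estimating
#' D on contiguous blocks of the track (block estimates are independent for
#' Brownian increments) and applying a t interval to the block mean.
#'
#' A quadratic lack-of-fit probe flags tracks whose MSD grows superlinearly
#' (e.g. drift, where MSD is quadratic in the lag), in which case the
#' diffusive interpretation of the slope is unreliable.
#'
#' @param positions Track positions in bp, regularly sampled.
#' @param dt Sampling interval in s.
#' @param max_lag Largest lag (default 10); must be far below the track
#'   length.
#' @param n_blocks Blocks for the CI (default 20).
#' @return A `fit_result`: `estimate` (D, bp^2/s), `ci95`, `residual_sd`
#'   (bp^2 about the fitted line), `warning_flag` (poor linearity), plus
#'   `msd` and `curvature_ratio`.
#' @export
estimate_diffusion_coefficient <- function(positions, dt, max_lag = 10L,
                                           n_blocks = 20L) {
  n <- length(positions)
  stopifnot(dt > 0, max_lag >= 1)
  if (max_lag >= n - 1)
    stop("max_lag (", max_lag, ") must be below the track length (", n, ")",
         call. = FALSE)
  lags <- seq_len(max_lag)
  fit_D <- function(x) {
    msd <- track_msd(x, lags)
    tau <- lags * dt
    slope <- sum(msd * tau / lags) / sum(tau^2 / lags) # WLS through origin, w = 1/lag
    list(D = slope / 2, msd = msd)
  }
  full <- fit_D(positions)
  tau <- lags * dt
  resid <- full$msd - 2 * full$D * tau
  # curvature probe: msd ~ c1 k + c2 k^2; large |c2| max_lag / |c1| means
  # superlinear growth (drift), linear diffusive fit unreliable
  qfit <- stats::lm(full$msd ~ 0 + lags + I(lags^2))
  c1 <- stats::coef(qfit)[["lags"]]
  c2 <- stats::coef(qfit)[["I(lags^2)"]]
  curv <- abs(c2) * max_lag / max(abs(c1), .Machine$double.eps)
  flagged <- curv > 0.2
  if (flagged)
    warning("MSD growth is not linear in lag (curvature ratio ",
            signif(curv, 3), "); diffusive fit unreliable")
  # block CI
  block_id <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  ok_blocks <- tabulate(block_id) > max_lag + 1
  bD <- vapply(which(ok_blocks), function(b)
    fit_D(positions[block_id == b])$D, numeric(1))
  B <- length(bD)
  ci <- if (B >= 3) {
    half <- stats::qt(0.975, B - 1) * stats::sd(bD) / sqrt(B)
    c(full$D - half, full$D + half)
  } else c(NA_real_, NA_real_)
  new_fit_result(full$D, ci, units = "bp^2/s",
                 residual_sd = stats::sd(resid),
                 warning_flag = flagged,
                 details = list(msd = full$msd, lags = lags,
                                curvature_ratio = curv))
}

#' qPCR fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_control)_galactose - (Ct_target -
#' Ct_control)_glucose`; the fold change of the target region (e.g. a
#' re-replication region against an internal control) is `2^-ddCt`.
#'
#' @param ct_target_gal,ct_control_gal Threshold cycles under galactose
#'   (induced).
#' @param ct_target_glu,ct_control_glu Threshold cycles under glucose
#'   (repressed).
#' @return Fold change (1 = no change).
#' @examples
#' ddct_fold_change(24, 20, 25, 20) # target one cycle earlier: fold 2
#' @export
ddct_fold_change <- function(ct_target_gal, ct_control_gal,
                             ct_target_glu, ct_control_glu) {
  cts <- c(ct_target_gal, ct_control_gal, ct_target_glu, ct_control_glu)
  stopifnot(all(is.finite(cts)), all(cts > 0))
  ddct <- (ct_target_gal - ct_control_gal) - (ct_target_glu - ct_control_glu)
  2^(-ddct)
}
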