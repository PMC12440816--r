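---
title: "Modeling MCM double-hexamer assembly by SH diffusion and collision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MCM double-hexamer assembly by SH diffusion and collision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmdh)
```

## The model

Licensing a budding-yeast replication origin ends with two Mcm2--7 single
hexamers (SHs) joined head-to-head into a double hexamer (DH). When the two
SHs are loaded independently at two ORC binding sites, DH formation requires
that they find each other by one-dimensional diffusion along the DNA before
either falls off. `mcmdh` implements that process as a stochastic
first-passage problem and the exact mathematics needed to validate it.

The ingredients are:

* **Loading geometry.** The two ORC sites point at each other; separation is
  measured between their 5' ends. ORC engages 6 bp ahead of its site and a
  loaded SH ring covers 35 bp, so each loaded SH+ORC occupies 41 bp past the
  origin and the two N-termini start `separation - 82` bp apart. A
  separation of 82 bp is therefore the closest possible loading arrangement
  -- the SHs are born touching and the DH forms immediately.
* **Diffusion.** SH sliding is ATP-independent, so displacements are thermal:
  per time step `dt` each SH moves by a mean-zero Gaussian with variance
  `2 D dt`, with `D = 800` bp^2/s taken from single-molecule fluorescence
  tracking. Both SHs step independently in every iteration.
* **Dissociation.** Each loaded SH leaves DNA with a measured half-life; per
  step each live SH dies with probability `1 - 2^(-dt/half_life)`. The first
  death ends the trajectory, because a lone SH cannot complete a DH.
* **Collision.** The first step at which the N-terminus-to-N-terminus gap is
  <= 0 bp is the collision; its time is the first-passage time, and the
  fraction of trajectories that collide before dissociation and before the
  20-min incubation horizon is the DH-formation efficiency.

## The dissociation hazard: a deliberate correction

The literal per-step dissociation rule one might write down from the
exponential lifetime law is its *density*, `(1/tau) exp(-t/tau)` with
`tau = half_life / ln 2`. That expression has units of 1/s, not a
probability: used directly as a per-step acceptance threshold it kills
essentially every SH within a second regardless of the configured
half-life, which contradicts the measured minutes-scale survival the rule
is meant to encode (the engine exposes this behaviour behind
`hazard_mode = "as_printed"`, and a test documents it). The default
`"memoryless"` mode instead applies the exact per-step hazard
`1 - 2^(-dt/half_life)`, which reproduces exponential survival with the
stated half-life at any step size; the survival-curve test verifies this to
within binomial error.

Two half-life values circulate for the same retention measurement: 3 min
(used by the simulation) and "approximately 3.5 min" (quoted with the
retention figure). Both ship as named presets
(`sh_half_life_presets`); the simulation default is 180 s, and the
retention-fitting demonstrations use 3.5 min as generator truth.

## The first-passage oracle

Because both SHs diffuse independently, the gap between their N-termini is
itself a Brownian motion with relative diffusion coefficient
`D_rel = 2 D`, started at `x0 = separation - 82` and absorbed at 0; SH
dissociation is an exponential "killing" of the pair at total rate
`k = 2 ln 2 / half_life`. The first-passage time to 0 follows the Levy
distribution

$$ f(t) = \frac{x_0}{\sqrt{4 \pi D_{rel} t^3}} e^{-x_0^2 / (4 D_{rel} t)} , $$

and the DH-formation probability within horizon T is
$\int_0^T f(t) e^{-kt} dt$, with the closed form
$\exp(-x_0 \sqrt{k / D_{rel}})$ at $T = \infty$. These results are exact
for the unbounded template and give three independent routes to the same
number: Gaussian stepping (`dh_formation_efficiency`), exact sampling of
collision and death times (`fast_outcome_sampler`, using
$T_{hit} = x_0^2 / (2 D_{rel} Z^2)$), and quadrature
(`collision_probability`). The test suite requires all three to agree
within Monte-Carlo error, which is the strongest correctness guarantee the
package offers: an error in the stepping engine's displacement variance,
hazard, or collision rule would shift its efficiency away from the
analytic value.

```{r oracle}
params <- diffusion_params() # D = 800 bp^2/s, half-life 3 min, T = 20 min
collision_probability(relative_process_from(300, params))
```

At the 300 bp separation used for the two-site collision assay this gives
~0.62: widely separated sites lose roughly half their DH yield to SH
dissociation during the diffusive search. The efficiency is maximal (exactly
1) at 82 bp and decays with separation; on the log scale the decay is
nearly linear in the initial gap with slope close to the analytic
$-\sqrt{k/D_{rel}}$, the exponential trend the finite-horizon curve
inherits from the closed form.

## Numerical choices

* **Time step.** The engine's default is 10 microseconds, the historical
  fidelity choice. The stated step criterion -- per-step MSD below 1 bp --
  actually permits `dt = 1/(2D) = 625` microseconds
  (`choose_time_step(800)`); the tighter historical value is kept as the
  default for fidelity, but stepping at 10 microseconds costs 1.2e8 steps
  per 20-min trajectory, so the tests and the shipped analyses run at
  `dt = 1` ms. That coarsening is legitimised not by the MSD criterion but
  by the oracle-equivalence tests: discrete end-of-step collision checking
  misses sub-step excursions below zero, an effect of order 0.58 times the
  per-step gap standard deviation (~1 bp at 1 ms) on the effective barrier
  position, which at the tested parameter sets is well inside Monte-Carlo
  error at 1,500--2,000 trajectories.
* **Boundaries.** The template is an unbounded line by default: real
  templates end, but the exponential trend of the measured efficiency curve
  matches the unbounded solution, SHs are observed to diffuse off origins,
  and the free-line oracle stays exact. `boundary_mode = "reflecting"`
  with a finite `template_length` is available (N-terminus positions fold
  back at the ends); the oracle refuses reflecting geometry, and a test
  verifies that confinement raises the meeting probability as it must.
* **Collision resolution.** Positions are continuous (bp units); both SHs
  move each step and the gap is tested once at the end of the full step,
  then survivors draw their dissociation Bernoulli. No within-step
  interpolation is attempted. At `x0 = 0` the collision time is exactly 0
  and is handled as a point mass, never through the density.
* **Quadrature.** The Levy density has an essential singularity at
  `t = 0`; the substitution `u = 1/t` removes it, and adaptive quadrature
  at absolute tolerance 1e-8 then agrees with the closed form to < 1e-6.
* **RNG.** The C++ engine uses its own counter-seeded generator
  (xoshiro256++ seeded by splitmix64) with one substream per trajectory
  index, so runs are bit-for-bit reproducible, independent of R's RNG
  state, and stable under any future parallel scheduling. R-level
  generators seed R's RNG locally and restore the caller's stream.

## Origin architecture by PWM

The motif module scores origins with a log-odds position weight matrix on
both strands (0-based half-open coordinates, reverse-strand hits reported
in forward coordinates), takes the best hit as the A-like (EACS) site, the
best opposite-strand hit as the B2-like site, and reports center-to-center
and inner-edge distances. Spacing classes follow the biochemistry: below
12 bp of inner-edge room only one ORC can bind at a time (10 bp is the
ARS1 A/B1-to-B2 distance; 2 bp more already admits two ORC); beyond the
cutoff two ORC bind simultaneously; 41 bp of room fits a loaded SH and
82 bp fits a DH between the sites. The simultaneous-binding cutoff is an
EMSA observation; the 41/82 bp thresholds are the package's own footprint
arithmetic, since no explicit values are published for those categories.

Scoring choices: `min_score` defaults to 60% of the PWM's maximum
achievable score; ties break leftmost then + strand so outputs are
deterministic; windows containing ambiguity codes are skipped with a
warning because their log-odds are undefined. The scanner is verified
against exhaustive per-window enumeration on short sequences.

The shipped matrix (`demo_pwm()`) is a synthetic 17 bp AT-rich
demonstration motif of EACS-like length. The genuine EACS matrix and the
genome-wide origin set are external resources, so the package makes no
claim to reproduce published genome-wide spacing fractions; what it does
guarantee, by construction and test, is exact recovery of planted
architectures and monotone degradation of recovery with mutation load.

## Assay inference

* **Two-site occupancy.** Distributing `n` SHs over `N` sites at random
  leaves a fraction `(n/N)^2` of two-site molecules doubly occupied under
  the independent-site approximation -- the arithmetic behind the
  150-fmol-on-300-fmol worked example (25%, 37.5 fmol). The approximation
  is the default because it is what that calculation uses;
  `exact_placement` mode gives the hypergeometric expectation
  `n(n-1)/(N(N-1))`, verified against direct enumeration and convergent to
  the independent value as the system grows. `predicted_max_yield` takes
  the collision efficiency as an explicit argument rather than assuming a
  value, because the published "around 50%" reduction at 300 bp is not
  unambiguously the model curve's 0.62.
* **Half-life fitting.** `fit_half_life` fits `A 2^(-t/half_life)` by OLS
  on the log2 scale -- the log transform is the variance stabilizer for
  the multiplicative noise of bead assays -- and attaches a seeded
  residual-bootstrap percentile CI (1,000 resamples; residual rather than
  pairs resampling because time-courses have few points). Non-decaying
  input returns a flagged infinite sentinel instead of an error.
* **Diffusion from tracks.** `estimate_diffusion_coefficient` regresses
  MSD over lags 1--10 through the origin with 1/lag weights and halves the
  slope. The CI comes from re-estimating D on 20 contiguous track blocks
  (independent for Brownian increments) with a t interval; a quadratic
  lack-of-fit probe flags superlinear MSD growth such as drift, where the
  diffusive reading of the slope is meaningless. A coverage test checks
  the interval traps the true D in at least 90 of 100 seeded replicates.
* **qPCR.** `ddct_fold_change` is the plain `2^-ddCt` formula with
  `ddCt = (Ct_target - Ct_control)_galactose - (Ct_target -
  Ct_control)_glucose`.

## What the synthetic data emulate -- and what they do not

The generators produce exactly the study conditions the analyses assume:
origin sequences of 400 bp with 60% AT background and planted opposed
consensus sites at controlled spacing and strength; retention time-courses
`A 2^(-t/half_life)(1 + eps)` at times 0--16 min with 5% multiplicative
Gaussian noise truncated at zero; Brownian tracks at a stated `D`. Each
generator returns (or writes alongside) its ground truth and is
deterministic under a fixed seed.

They deliberately omit: nucleosome positioning and chromatin context,
sequence-dependent sliding friction, LacI roadblocks (the 300 bp lacO
fixture records the roadblock flag but the engine does not model it --
modeling reversible obstacles is out of scope), photophysics and
localization error in tracking data, and baseline offsets in retention
assays. Passing parameter-recovery tests therefore demonstrates estimator
correctness under the model's own assumptions, not robustness to the full
messiness of the corresponding experiments.

## Problem sizes

The shipped analyses and tests use: 2,000 stepping trajectories per
separation at `dt = 1` ms for the published grid (82--300 bp), 20,000
fast-sampler trajectories per point for fine sweeps, 10,000 lifetimes for
the survival median, 100 tracks of 1e4 steps for diffusion recovery, and
200 replicate time-courses for half-life recovery. These sizes put
Monte-Carlo error well below the effect sizes under test while keeping any
single analysis in the seconds-to-minutes range.

## Known limitations

* The stepping engine's collision test is end-of-step only; at step sizes
  much coarser than 1 ms the discretization bias would eventually exceed
  Monte-Carlo error, and the oracle-equivalence test is the guard rail.
* The oracle is exact only for the unbounded line; reflecting-boundary
  runs are validated by self-consistency and qualitative confinement
  behaviour, not by closed form.
* Occupancy arithmetic treats sites as equivalent and ignores cooperative
  or sequential loading.
* The architecture analysis is only as good as the PWM supplied; with the
  demonstration matrix it characterizes synthetic origins, not the yeast
  genome.
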