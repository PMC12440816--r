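# mcmdh

Stochastic modeling of MCM double-hexamer (DH) assembly at budding-yeast
replication origins.

Origin licensing ends with two Mcm2–7 single hexamers (SHs) locked into a
head-to-head DH. When the two SHs are loaded independently from two ORC
binding sites, the DH can only form if the SHs — sliding passively along the
DNA — collide before either one dissociates. `mcmdh` is for researchers who
want to quantify that pathway: it simulates the collision process, solves it
exactly, analyzes the ORC-binding-site architecture of origin sequences, and
performs the small inference calculations that surround the corresponding
biochemical assays.

## The model

Two SHs are loaded with N-termini facing, starting
`x0 = separation − 2·(6 + 35)` bp apart (6 bp ORC overhang + 35 bp SH
footprint per side; 82 bp is the closest possible loading separation). Each
SH takes Gaussian steps of variance `2·D·Δt` (`D = 800 bp²/s` from
single-molecule tracking) and dissociates per step with probability
`1 − 2^(−Δt/τ½)` (`τ½ = 3 min`). The first instant the gap reaches 0 is the
collision — the first-passage time — and the DH-formation efficiency is the
probability of collision within the 20-min incubation, before either SH
dies.

Because the gap between the SHs is itself Brownian
(`D_rel = 2D`) with exponential killing at rate `k = 2·ln2/τ½`, the model
has an exact solution: collision times follow the Lévy law
`f(t) = x0/√(4π·D_rel·t³)·exp(−x0²/(4·D_rel·t))`, the efficiency is
`∫₀ᵀ f(t)·e^(−kt) dt`, and at `T = ∞` it reduces to
`exp(−x0·√(k/D_rel))`. The package ships the stepping engine, an exact
sampler, and the quadrature/closed forms, and its tests require all three
routes to agree.

Alongside the simulator: PWM scanning of origins for the best EACS-like
match and best opposed B2-like match with spacing classification
(single-ORC / two-ORC / fits-an-SH / fits-a-DH), two-site occupancy
arithmetic, exponential half-life fitting with bootstrap CIs,
diffusion-coefficient estimation from tracks by MSD regression, the qPCR
`2^−ΔΔCt` formula, and seeded synthetic-data generators with ground truth
for every input the pipeline consumes.

## Worked example

```r
library(mcmdh)

params <- diffusion_params(dt = 1e-3)  # D = 800 bp²/s, τ½ = 3 min, T = 20 min
sweep_separations(c(82, 90, 150, 300), params, n_trajectories = 2000, seed = 1)
#>   separation_bp  p_dh   mc_se relative_efficiency n_collision n_dissociation n_timeout
#> 1            82 1.000 0.00000               1.000        2000              0         0
#> 2            90 0.975 0.00352               0.975        1949             51         0
#> 3           150 0.858 0.00780               0.858        1716            284         0
#> 4           300 0.601 0.01095               0.601        1202            798         0
```

At 82 bp the SHs are loaded touching, so every trajectory collides at t = 0;
by 300 bp roughly 40% of SH pairs lose a partner to dissociation before
meeting (the analytic value is `collision_probability(relative_process_from(300,
params))` = 0.620, within Monte-Carlo error of the simulated 0.601).

```r
occ <- two_site_double_occupancy(150, 300)   # 150 fmol SH on 300 fmol sites
#> doubly occupied: 25% of molecules (37.5 fmol)

tc <- gen_retention_timecourse(3.5, noise_cv = 0.05, seed = 2)
fit_half_life(tc$time, tc$signal, seed = 3)
#> Fit: 3.492 time units of input (95% CI 3.378 - 3.634)
```

The occupancy call reproduces the two-site loading arithmetic (only a
quarter of molecules carry the two SHs a DH requires), and the retention fit
recovers the 3.5-min generating half-life from a noisy five-point
time-course.

The `analysis/` directory holds three narrative drivers —
`01_sweep_efficiency.R` (efficiency-vs-separation curves by stepping engine,
exact sampler, and quadrature), `02_origin_architecture.R` (synthetic origin
set scanned into architecture tables, BED hits, and spacing-class
fractions), `03_assay_inference.R` (occupancy, predicted yield, half-life,
diffusion coefficient, qPCR fold change) — each writing TSVs with
provenance headers under `results/`. The methods vignette
(`vignettes/dh-assembly-model.Rmd`) documents the model, its numerical
choices, and its limitations.

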