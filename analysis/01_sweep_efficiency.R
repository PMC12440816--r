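#!/usr/bin/env Rscript
# DH-formation efficiency as a function of ORC-binding-site separation.
#
# Two SHs loaded head-to-head diffuse on the template (D = 800 bp^2/s),
# dissociate with a 3 min half-life, and form a DH on first contact; the
# efficiency is the probability of contact within the 20 min incubation.
# The stepping engine (1 ms steps) runs the published separation grid; the
# exact first-passage sampler then sweeps a fine grid cheaply and the
# analytic collision probability is tabulated alongside.

suppressPackageStartupMessages(library(mcmdh))

dir.create("results", showWarnings = FALSE)
cfg <- read_run_config(system.file("extdata", "run_config.yaml",
                                   package = "mcmdh"))
params <- cfg$params # D = 800 bp^2/s, half-life 3 min, T = 20 min, dt = 1 ms
seps <- cfg$separations
seed <- cfg$seed

message("Stepping-engine sweep over {", paste(seps, collapse = ", "), "} bp ...")
sweep <- sweep_separations(seps, params, n_trajectories = cfg$n_trajectories,
                           seed = seed)
write_result_tsv(sweep, "results/efficiency_sweep_stepping.tsv", seed = seed,
                 params = list(engine = "stepping", dt_s = params$dt,
                               D = params$D, half_life_s = params$half_life))

peak <- sweep$separation_bp[which.max(sweep$p_dh)]
message("Efficiency is maximal at ", peak,
        " bp (the closest-loading separation); p_DH there = ",
        signif(max(sweep$p_dh), 3))
message("At 300 bp the relative efficiency has fallen to ",
        signif(sweep$relative_efficiency[sweep$separation_bp == 300], 2),
        ": widely spaced sites lose roughly half their DH-formation ",
        "probability to SH dissociation during the search.")

fine <- seq(82, 400, by = 2)
fast <- sweep_separations(fine, params, n_trajectories = 20000, seed = seed,
                          engine = "fast")
fast$analytic_p <- vapply(fine, function(s)
  collision_probability(relative_process_from(s, params)), numeric(1))
write_result_tsv(fast, "results/efficiency_sweep_fast.tsv", seed = seed,
                 params = list(engine = "fast"))

# log-efficiency is close to linear in the initial gap (exponential trend)
x0 <- initial_gap(fine[-1])
trend <- stats::lm(log(fast$p_dh[-1]) ~ x0)
message("log p_DH vs initial gap: slope ", signif(coef(trend)[2], 3),
        " per bp, R^2 = ", signif(summary(trend)$r.squared, 4),
        " (analytic slope -sqrt(k/D_rel) = ",
        signif(-sqrt(2 * log(2) / params$half_life / (2 * params$D)), 3), ")")
message("Tables written to results/.")
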