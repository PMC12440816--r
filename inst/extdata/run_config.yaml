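# Default simulation configuration: the measured kinetics of SH diffusion
# and dissociation on DNA, swept over the standard separation grid.
D_bp2_per_s: 800
dt_s: 0.001
half_life_s: 180
total_time_s: 1200
separations: [82, 90, 110, 150, 200, 250, 300]
n_trajectories: 2000
seed: 1
hazard_mode: memoryless
boundary_mode: unbounded
engine: stepping
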