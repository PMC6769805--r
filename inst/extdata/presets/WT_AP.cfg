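# WT_AP condition preset: wild type at ambient pressure reference state.
condition = WT_AP
residue_table = WT_AP_residues.tsv
dihedral_table = WT_AP_dihedrals.tsv

# pressure series (MPa) and measurement noise (ppm)
pressures = 5, 29.444, 53.889, 78.333, 102.778, 127.222, 151.667, 176.111, 200.556, 225
noise_sd = 0.002

# two-state thermodynamics (excited minus ground)
dG0 = 15000            # J/mol
dV = -100              # mL/mol
temperature = 298      # K

# latent conformational chain (3 subensembles; off-diagonal mass split evenly)
n_states = 3
stay_prob = 0.995

# D76(Od2)-K41(Nz) distance subensembles, Angstrom
distance_means = 3, 6, 10
distance_sds = 0.4, 0.4, 0.4

# collective-motion trajectory
mode_amplitude_sd = 3.0    # Angstrom, dominant bending mode
traj_noise_sd = 0.3        # Angstrom, isotropic

# pH unfolding (tryptophan fluorescence, acid-unfolded)
unfold_midpoint = 4.11
unfold_slope = 1.5
unfold_baselines = 1.0, 0.3

# H/D exchange context: no aggregation channel for WT
k_agg_per_min = 0
pD_reading = 4.6
hdx_temperature = 298
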