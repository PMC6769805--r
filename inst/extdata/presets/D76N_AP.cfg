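# D76N_AP condition preset: aggregation-prone mutant at ambient pressure.
# Single conformational subensemble; mutation offsets on the contact network.
condition = D76N_AP
residue_table = D76N_AP_residues.tsv
dihedral_table = D76N_AP_dihedrals.tsv

pressures = 5, 29.444, 53.889, 78.333, 102.778, 127.222, 151.667, 176.111, 200.556, 225
noise_sd = 0.002

dG0 = 15000
dV = -100
temperature = 298

n_states = 1
stay_prob = 1

distance_means = 6
distance_sds = 0.4

mode_amplitude_sd = 0.8
traj_noise_sd = 0.3

unfold_midpoint = 4.54
unfold_slope = 1.5
unfold_baselines = 1.0, 0.3

# concurrent aggregation during exchange (methyl-signal decay), per minute
k_agg_per_min = 0.002
pD_reading = 5.1
hdx_temperature = 298
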