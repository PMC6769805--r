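# Reference constants for nearest-neighbour intrinsic amide exchange
# prediction in D2O (poly-DL-alanine reference, 20 C), Bai-type model.
# Rates: log10 of M^-1 min^-1 (acid, base) and min^-1 (water).
log_kA_ref = 1.62
log_kB_ref = 10.05
log_kW_ref = -1.5
# Arrhenius activation energies, kcal/mol
Ea_acid = 14.0
Ea_base = 17.0
Ea_water = 19.0
# D2O ion product and reference temperature
pKD = 15.05
T_ref = 293.15
# glass-electrode correction added to pD readings
pD_correction = 0.4
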