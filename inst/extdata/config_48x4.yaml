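# Proposed commercial instrument preset: 48 drugs x 4 dilutions,
# combinations of 4, canonical dilution layout (ring i = dilution level i,
# radius j = drug j; level 0 is the most concentrated stock).
n_rings: 4
n_radii: 48
combo_order: 4
n_dilutions: 4
seconds_per_position: 10
droplets_per_position_ml: 192
layout: dilution
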