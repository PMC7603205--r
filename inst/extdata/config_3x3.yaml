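# Introductory three-ring, three-radius build: 3 drugs x 3 dilutions,
# combinations of 3 (84 unreduced combinations, 27 meaningful).
n_rings: 3
n_radii: 3
combo_order: 3
n_dilutions: 3
seconds_per_position: 10
droplets_per_position_ml: 192
layout: dilution
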