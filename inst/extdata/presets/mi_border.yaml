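# MI-BORDER preset: infarct border zone, 7 days after coronary ligation
# (injury at 14 days post-induction).
recombination_efficiency: 0.466
colour_probs: {YFP: 0.529, RFP: 0.188, nGFP: 0.265, mCFP: 0.088} # normalized on load
founder_density: 67.3
clone_size_mean: 10.3
clone_size_sd: 10.6
single_cell_fraction: 0.634
edu_window_fraction: 0.585
edu_background_rate: 0.019
polychromatic_target: 0.093
region: border
seed: ~
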