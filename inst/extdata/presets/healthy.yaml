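# HEALTHY preset: uninjured adult mouse left ventricle, 21 days after
# tamoxifen induction of the Pdgfb-driven Confetti reporter.
recombination_efficiency: 0.466
colour_probs: {YFP: 0.519, RFP: 0.257, nGFP: 0.113, mCFP: 0.118} # normalized on load
founder_density: 72.3
clone_size_mean: 4.0
clone_size_sd: 2.1
single_cell_fraction: 0.546
edu_window_fraction: 0.285
edu_background_rate: 0.0009
polychromatic_target: 0.255
region: healthy
seed: ~
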