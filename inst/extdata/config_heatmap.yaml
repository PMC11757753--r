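# Size-variance heat map with the default protocol: J0 = G - I, C = 1,
# D = (1, 10), 15 log-spaced radii bracketing gamma = 1 per network size.
experiment: heatmap
n_values: [2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
n_samples: 1000
seed: 1
k_step: 0.05
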