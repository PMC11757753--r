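# Latin-hypercube screen of the two-node activator-inhibitor circuit.
topology: gierer_meinhardt
n_samples: 1000
seed: 1
k_step: 0.05
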