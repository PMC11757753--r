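# Example 3-node Turing-type circuit: the two diffusing species form an
# activator-inhibitor pair and one immobile node closes an extra negative
# feedback loop onto the activator. Illustrative design, not a transcription
# of any particular published circuit.
# Row i = regulated node, column j = regulator (J-oriented); +1 activation,
# -1 inhibition, 0 absent.
activator	inhibitor	immobile1
1	-1	-1
1	-1	0
1	0	0
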