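# Example 4-node circuit: two coupled activator-inhibitor modules. Nodes 1-2
# form the diffusing Gierer-Meinhardt pair; nodes 3-4 form a second, immobile
# activator-inhibitor module, coupled by activation 1->3 and inhibition 2->4.
# Illustrative design in the Gierer-Meinhardt family, not a transcription of
# any particular published circuit.
# Row i = regulated node, column j = regulator (J-oriented); +1 activation,
# -1 inhibition, 0 absent.
activator	inhibitor	immobile1	immobile2
1	-1	0	0
1	-1	0	0
1	0	1	-1
0	-1	1	-1
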