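geneA	geneB	combined_score
A	B	1
B	C	1
D	E	0.5
D	F	0.25
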