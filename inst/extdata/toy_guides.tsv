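seq	efficiency
AUGCU	1.5
AAAAA	-0.2
ACGTA	0.7
TTTTG	0.1
GCGCG	-1.1
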