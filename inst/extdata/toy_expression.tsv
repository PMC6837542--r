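gene	value
A	1
B	1
C	1
D	1
E	2
F	4
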