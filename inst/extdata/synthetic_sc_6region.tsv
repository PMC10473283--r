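L1	L2	L3	R1	R2	R3
0	124	0	107	0	42
124	0	37	0	70	0
0	37	0	0	95	143
107	0	0	0	0	0
0	70	95	0	0	0
42	0	143	0	0	0
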