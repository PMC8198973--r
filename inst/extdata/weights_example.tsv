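position	mutation	weight
16126	16126C	0.475
	transition	1.312
	transversion	1.593
	insertion	1.0
	deletion	1.0
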