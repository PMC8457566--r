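label	interventions	effect_percent
WT	.	0
odr-3	odr-3	66
ife-2	ife-2	55
odr-3; ife-2	odr-3,ife-2	187
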