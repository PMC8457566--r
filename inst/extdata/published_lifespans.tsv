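label	interventions	modes	arm	mean_lifespan	sem	p_value
WT(EV)	.	.	both	20.6	0.2	NA
odr-3	odr-3	mutation	both	26.0	0.3	2e-16
ife-2	ife-2	rnai	full	24.3	0.2	2e-16
cku-70	cku-70	rnai	full	21.5	0.2	7e-03
ife-2;EV	ife-2	rnai_diluted	ev	22.9	0.3	1e-10
cku-70;EV	cku-70	rnai_diluted	ev	21.9	0.2	1e-04
odr-3; ife-2	odr-3,ife-2	mutation,rnai	full	28.9	0.4	2e-16
odr-3; ife-2;EV	odr-3,ife-2	mutation,rnai_diluted	ev	30.1	0.5	2e-16
odr-3; cku-70	odr-3,cku-70	mutation,rnai	full	23.4	0.5	4e-11
odr-3; cku-70;EV	odr-3,cku-70	mutation,rnai_diluted	ev	26.5	0.4	2e-16
ife-2; cku-70	ife-2,cku-70	rnai_diluted,rnai_diluted	ev	23.7	0.3	3e-16
odr-3; ife-2; cku-70	odr-3,ife-2,cku-70	mutation,rnai_diluted,rnai_diluted	ev	27.9	0.3	2e-16
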