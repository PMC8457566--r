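strain	mean_mobile	mean_impaired	mean_frail	mean_lifespan
WT(EV)	17.3	1.5	1.8	20.6
odr-3	20.8	2.6	2.6	26.0
ife-2	21.0	1.6	1.7	24.3
odr-3; ife-2	25.0	2.2	1.7	28.9
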