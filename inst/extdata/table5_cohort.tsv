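stratification	category	pc	controls
age	43-50	26	5
age	51-60	135	18
age	61-70	165	25
age	>70	18	4
gleason	7	227	0
gleason	8	43	0
gleason	9	72	0
gleason	10	2	0
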