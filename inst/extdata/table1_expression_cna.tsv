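alteration	gene	position
up_amplified	AMY2B	1p21.1
up_amplified	CLEC18B	16q23.1
up_amplified	DPY19L2	12q14.2
up_amplified	GUSBP3	5q13.2
up_amplified	LOC157381	8q24.21
up_amplified	LOC391322	22q11.23
up_amplified	LOC728855	1q21.2
up_amplified	MLIP	6p12.1
up_amplified	POU5F1B	8q24.21
up_amplified	PVT1	8q24.21
up_amplified	SYCE1	10q26.3
up_amplified	TARP	7p14.1
up_amplified	TRIB1	8q24.21
up_amplified	ZDHHC11	5p15.33
down_deleted	ADAMTSL3	15q25.2
down_deleted	ADRA1A	8p21.2
down_deleted	CES1P1	16q12.2
down_deleted	CHRFAM7A	15q13.2
down_deleted	CLU	8p21.2
down_deleted	DMBT1	10q26.13
down_deleted	EPHA3	3p11.1
down_deleted	ETS2	21q22.2
down_deleted	EYA1	8q13.3
down_deleted	FCGR3B	1q23.3
down_deleted	FILIP1	6q14.1
down_deleted	FMN2	1q43
down_deleted	GSTM1	1p13.3
down_deleted	HSPA6	1q23.3
down_deleted	HSPA7	1q23.3
down_deleted	KLF5	13q22.1
down_deleted	MPP2	17q21.31
down_deleted	NAGS	17q21.31
down_deleted	PNMA2	8p21.2
down_deleted	SCARA3	8p21.2
down_deleted	SPG20	13q13.3
down_deleted	THSD7B	2q22.1
down_deleted	TP63	3q28
down_deleted	ZNF826P	19p12
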