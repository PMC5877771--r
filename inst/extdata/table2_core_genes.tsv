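alteration	gene	mirnas
up_amplified	TRIB1	hsa-miR-10a
up_amplified	ZDHHC11	hsa-miR-552
up_amplified	DPY19L2	hsa-miR-323-3p
down_deleted	CLU	hsa-miR-217
down_deleted	SCARA3	hsa-miR-182
down_deleted	TP63	hsa-miR-141, hsa-miR-217
down_deleted	HSPA6	hsa-miR-17
down_deleted	EYA1	hsa-miR-103
down_deleted	MPP2	hsa-miR-103
down_deleted	FILIP1	hsa-miR-129-5p
down_deleted	DMBT1	hsa-miR-197
down_deleted	NAGS	hsa-miR-506
down_deleted	PNMA2	hsa-miR-183, hsa-miR-217
down_deleted	THSD7B	hsa-miR-183
down_deleted	FCGR3B	hsa-miR-149
down_deleted	KLF5	hsa-miR-148a, hsa-miR-217, hsa-miR-182, hsa-miR-141
down_deleted	FMN2	hsa-miR-101
down_deleted	ETS2	hsa-miR-182
down_deleted	SPG20	hsa-miR-17
down_deleted	EPHA3	hsa-miR-182, hsa-miR-103, hsa-miR-197, hsa-miR-153, hsa-let-7f, hsa-miR-506, hsa-miR-454, hsa-miR-507, hsa-miR-196a, hsa-miR-489, hsa-miR-513a-3p, hsa-miR-1283, hsa-miR-103
down_deleted	ADAMTSL3	hsa-miR-103, hsa-miR-101, hsa-miR-19a/b, hsa-miR-491-3p, hsa-miR-19b, hsa-miR-129-5p, hsa-miR-142-5p, hsa-miR-155, hsa-miR-15b, hsa-miR-507, hsa-miR-512-5p, hsa-miR-513a-5p/3p, hsa-miR-103
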