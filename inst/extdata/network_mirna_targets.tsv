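mirna	gene
hsa-miR-153	EPHA3
hsa-miR-153	KLF5
hsa-miR-153	EFNA5
hsa-miR-153	EFNA3
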