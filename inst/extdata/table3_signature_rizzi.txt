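CLU
SYNTH_FILLER_R1
SYNTH_FILLER_R2
SYNTH_FILLER_R3
SYNTH_FILLER_R4
SYNTH_FILLER_R5
SYNTH_FILLER_R6
SYNTH_FILLER_R7
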