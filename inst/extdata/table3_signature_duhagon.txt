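KLF5
SYNTH_FILLER_D01
SYNTH_FILLER_D02
SYNTH_FILLER_D03
SYNTH_FILLER_D04
SYNTH_FILLER_D05
SYNTH_FILLER_D06
SYNTH_FILLER_D07
SYNTH_FILLER_D08
SYNTH_FILLER_D09
SYNTH_FILLER_D10
SYNTH_FILLER_D11
SYNTH_FILLER_D12
SYNTH_FILLER_D13
SYNTH_FILLER_D14
SYNTH_FILLER_D15
SYNTH_FILLER_D16
SYNTH_FILLER_D17
SYNTH_FILLER_D18
SYNTH_FILLER_D19
SYNTH_FILLER_D20
SYNTH_FILLER_D21
SYNTH_FILLER_D22
SYNTH_FILLER_D23
SYNTH_FILLER_D24
SYNTH_FILLER_D25
SYNTH_FILLER_D26
SYNTH_FILLER_D27
SYNTH_FILLER_D28
SYNTH_FILLER_D29
SYNTH_FILLER_D30
SYNTH_FILLER_D31
SYNTH_FILLER_D32
SYNTH_FILLER_D33
SYNTH_FILLER_D34
SYNTH_FILLER_D35
SYNTH_FILLER_D36
SYNTH_FILLER_D37
SYNTH_FILLER_D38
SYNTH_FILLER_D39
SYNTH_FILLER_D40
SYNTH_FILLER_D41
SYNTH_FILLER_D42
SYNTH_FILLER_D43
SYNTH_FILLER_D44
SYNTH_FILLER_D45
SYNTH_FILLER_D46
SYNTH_FILLER_D47
SYNTH_FILLER_D48
SYNTH_FILLER_D49
SYNTH_FILLER_D50
SYNTH_FILLER_D51
SYNTH_FILLER_D52
SYNTH_FILLER_D53
SYNTH_FILLER_D54
SYNTH_FILLER_D55
SYNTH_FILLER_D56
SYNTH_FILLER_D57
SYNTH_FILLER_D58
SYNTH_FILLER_D59
SYNTH_FILLER_D60
SYNTH_FILLER_D61
SYNTH_FILLER_D62
SYNTH_FILLER_D63
SYNTH_FILLER_D64
SYNTH_FILLER_D65
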