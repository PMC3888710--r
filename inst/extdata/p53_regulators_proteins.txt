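BRCA1
HDAC1
PLK1
PML
CDKN2A
SMAD1
WT1
RB1
YY1
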