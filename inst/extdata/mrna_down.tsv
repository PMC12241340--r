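gene_id
CCND1
ROBO4
MMP1
ADGRG1
RHOB
UHRF1
GXYLT1
EOGT
MICALL1
NPAS2
TXN2
ARHGAP1
EIF4EBP2
MAVS
E2F4
HBEGF
PRIM1
TGFBR2
COL4A1
LBR
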