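circ_id	rbp
circ_0001522	AGO2
circ_0001522	CPSF7
circ_0001522	TARDBP
circ_0001522	UPF1
circ_0001522	LIN28B
circ_0001522	IGF2BP2
circ_0001522	YTHDC1
circ_0001522	CPSF6
circ_0001522	YTHDF1
circ_0001522	IGF2BP1
circ_0001522	CELF2
circ_0001522	U2AF65
circ_0001522	SF3B1
circ_0001522	CSTF2
circ_0001522	CSTF2T
circ_0001522	CPSF4
circ_0001522	HNRNPC
circ_0001522	SRSF1
circ_0001522	FMR1
circ_0001522	CPSF1
circ_0001278	AGO2
circ_0001278	CPSF7
circ_0001278	TARDBP
circ_0001278	UPF1
circ_0001278	LIN28B
circ_0001278	ATXN2
circ_0001278	NUDT21
circ_0001278	FBL
circ_0001278	YTHDF2
circ_0001278	PPIG
circ_0001278	YBX3
circ_0001278	ZNF800
circ_0001278	BCLAF1
circ_0001278	FUS
circ_0001278	RBM15
circ_0001278	HNRNPA1
circ_0001278	IGF2BP1
circ_0001801	AGO2
circ_0001801	CPSF7
circ_0001801	TARDBP
circ_0001801	UPF1
circ_0001801	LIN28B
circ_0001801	IGF2BP2
circ_0001801	YTHDC1
circ_0001801	FUS
circ_0001801	HNRNPA1
circ_0001801	YBX3
circ_0001801	SRSF1
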