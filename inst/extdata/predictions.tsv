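circ_id	mirna_id	source	score
circ_0001522	hsa-miR-579-3p	miranda	152
circ_0001522	miR-579-3p	rna22	0.82
circ_0001522	hsa-miR-4458	miranda	148
circ_0001522	hsa-miR-4458	rna22	0.79
circ_0001522	hsa-miR-21-5p	miranda	140
circ_0001278	hsa-let-7c-5p	miranda	161
circ_0001278	let-7c-5p	rna22	0.88
circ_0001278	hsa-miR-145-5p	miranda	155
circ_0001278	hsa-miR-145-5p	rna22	0.84
circ_0001278	hsa-miR-4458	miranda	150
circ_0001278	hsa-miR-4458	rna22	0.80
circ_0001278	hsa-miR-100-5p	rna22	0.71
circ_0001801	hsa-miR-29b-2-5p	miranda	158
circ_0001801	hsa-miR-29b-2-5p	rna22	0.86
circ_0001801	hsa-miR-760	miranda	149
circ_0001801	hsa-miR-760	rna22	0.81
circ_0001801	hsa-miR-7977	miranda	146
circ_0001801	hsa-miR-7977	rna22	0.77
circ_0001801	hsa-miR-9-5p	miranda	133
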