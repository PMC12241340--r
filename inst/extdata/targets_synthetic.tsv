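mirna_id	target_gene	evidence
hsa-miR-4458	CCND1	experimentally_observed
hsa-miR-4458	UHRF1	high_confidence
hsa-miR-4458	EOGT	high_confidence
hsa-miR-145-5p	ROBO4	experimentally_observed
hsa-miR-145-5p	RHOB	experimentally_observed
hsa-miR-145-5p	MICALL1	high_confidence
hsa-miR-760	MMP1	high_confidence
hsa-miR-760	ARHGAP1	high_confidence
hsa-miR-579-3p	ADGRG1	high_confidence
hsa-miR-579-3p	TGFBR2	high_confidence
hsa-let-7c-5p	CCND1	experimentally_observed
hsa-let-7c-5p	E2F4	high_confidence
hsa-miR-29b-2-5p	COL4A1	experimentally_observed
hsa-miR-29b-2-5p	PRIM1	high_confidence
hsa-miR-7977	LBR	high_confidence
hsa-miR-7977	MAVS	high_confidence
hsa-miR-21-5p	PTEN	experimentally_observed
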