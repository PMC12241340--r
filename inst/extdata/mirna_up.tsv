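mirna_id
miR-579-3p
miR-4458
let-7c-5p
miR-145-5p
miR-29b-2-5p
miR-760
miR-7977
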