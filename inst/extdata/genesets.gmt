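TERM_A	angiogenesis-like toy set	GENE1	GENE2
TERM_B	metabolism-like toy set	GENE3
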