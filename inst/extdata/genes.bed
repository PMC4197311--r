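1	1000	2000	GENE1	0	+
1	249999	260000	GENE2	0	-
2	5000	6000	GENE3	0	+
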