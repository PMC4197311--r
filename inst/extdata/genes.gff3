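##gff-version 3
1	toy	gene	1001	2000	.	+	.	ID=GENE1;gene_id=GENE1
1	toy	gene	250000	260000	.	-	.	ID=GENE2;gene_id=GENE2
2	toy	gene	5001	6000	.	+	.	ID=GENE3;gene_id=GENE3
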