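gene_name	synonyms	gene_id	organism	motif	len	experiment	pubmed	domain	matrix_id	quality_score
SRSF1	SFRS1	ENSG00000136450	Homo sapiens	ACGCGCC	7	SELEX	7510720	RRM	M001	1
SRSF1	SFRS1	ENSG00000136450	Homo sapiens	RCGUUC	6	SELEX	7510720	RRM	M002	0.5
RBM8A		ENSG00000131795	Homo sapiens	ACGCGCC	7	RNAcompete	18447585	RRM	M001	1
CELF1	CUGBP1;BRUNOL2	ENSG00000149187	Homo sapiens	UGUU	4	SELEX	9371827	RRM	M003	0.25
PTBP1		ENSMUSG00000006498	Mus musculus	UCUUC	5	EMSA	1717261	RRM	M004	1
HNRNPA1	HNRPA1	ENSG00000135486	Homo sapiens	UAGGGW	6	SELEX	8174554	RRM	M005	0.75
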