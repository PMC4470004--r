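mirna_id	tf_gene_id	regulation	pubmed
mir-f2	ENSG00000000004	activation	20000001
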