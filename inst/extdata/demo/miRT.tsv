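gene_id	mirna_id	pubmed
ENSG00000000002	mir-f1	10000001
ENSG00000000004	mir-f2	10000002
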