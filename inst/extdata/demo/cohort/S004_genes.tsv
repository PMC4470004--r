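feature_id	value
ENSG00000000001	22.1832720962192
ENSG00000000002	15.8533364053173
ENSG00000000003	16.9691155155871
ENSG00000000004	19.830403817012
ENSG00000000005	11.3723082183681
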