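feature_id	value
ENSG00000000001	18.2686494078661
ENSG00000000002	20.6818495464541
ENSG00000000003	30.1315455969648
ENSG00000000004	14.0952156797752
ENSG00000000005	42.6823134455123
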