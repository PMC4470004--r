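feature_id	value
ENSG00000000001	188.416206335598
ENSG00000000002	160.763908693046
ENSG00000000003	100.765679857166
ENSG00000000004	19.3470788755955
ENSG00000000005	14.8207426125215
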