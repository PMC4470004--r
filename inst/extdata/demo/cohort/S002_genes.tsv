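feature_id	value
ENSG00000000001	153.612787034149
ENSG00000000002	107.194415598363
ENSG00000000003	129.848935891341
ENSG00000000004	21.8941071122359
ENSG00000000005	18.4448631701046
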