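feature_id	value
mir-f1	1.04151520440721
mir-f2	8.38491233841924
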