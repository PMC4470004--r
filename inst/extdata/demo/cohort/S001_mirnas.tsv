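feature_id	value
mir-f1	0.896468774747119
mir-f2	12.5749708796253
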