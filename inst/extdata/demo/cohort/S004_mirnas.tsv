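feature_id	value
mir-f1	8.7727305764738
mir-f2	13.4582476639873
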