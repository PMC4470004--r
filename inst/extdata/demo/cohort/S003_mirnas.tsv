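feature_id	value
mir-f1	13.4932198653412
mir-f2	10.1406788513935
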