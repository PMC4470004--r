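sample_id	true_label
S001	responder
S002	responder
S003	non-responder
S004	non-responder
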