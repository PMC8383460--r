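quantity	value
text_mined_diseases	6263
semi_automatic_diseases	7610
overlap	4118
universe	19133
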