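dataset	tp	fp	fn
semiauto_strict	568	81	262
semiauto_soft	2454	376	1045
textmine_rank16_strict	143	425	687
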