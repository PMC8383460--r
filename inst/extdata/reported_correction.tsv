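dataset	n_relabelled	residual_fp
textmine_rank16_strict	376	47
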