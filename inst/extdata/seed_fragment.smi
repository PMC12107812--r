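OCc1ccccc1	benzyl_alcohol_seed_fragment
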