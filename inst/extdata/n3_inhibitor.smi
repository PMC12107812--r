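CC(C)C[C@H](NC(=O)[C@@H](NC(=O)[C@H](C)NC(=O)c1cc(C)on1)C(C)C)C(=O)N[C@@H](C[C@@H]2CCNC2=O)/C=C/C(=O)OCc1ccccc1	N3_peptidomimetic_inhibitor
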