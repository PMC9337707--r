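snp	a1	a2	z
snp1	A	G	6
snp2	A	G	7
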