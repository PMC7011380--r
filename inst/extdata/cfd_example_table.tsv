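rna_base	dna_base	position	score
G	A	6	0.67
C	T	10	0.87
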