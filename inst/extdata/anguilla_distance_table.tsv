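species_a	species_b	code_a	code_b	k2p	se	differences
A. japonica	A. marmorata	J	M	0.050	0.011	22
A. japonica	A. bicolor pacifica	J	B	0.055	0.011	24
A. japonica	A. anguilla	J	A	0.053	0.011	23
A. marmorata	A. bicolor pacifica	M	B	0.044	0.010	20
A. marmorata	A. anguilla	M	A	0.061	0.012	27
A. bicolor pacifica	A. anguilla	B	A	0.057	0.011	25
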