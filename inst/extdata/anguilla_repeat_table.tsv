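locus	species	species_code	ta	n_sequences	notation
AJ-1	A. japonica	J	58	11	(TG)_7~13
AJ-1	A. marmorata	M	54	17	(TG)_6, 7, 8, 10; TC(TG)_6
AJ-1	A. anguilla	A	54	10	(TG)_5~10
AJ-1	A. bicolor pacifica	B	54	11	(TG)_7~9
AJ-8	A. japonica	J	56	12	(TG)_14~18, 20
AJ-8	A. marmorata	M	52	2	(TG)_14, 15
AJ-8	A. anguilla	A	52	11	(TG)_12, 13, 15, 17, 19; (TG)_6(TA)(TG)_11
AJ-8	A. bicolor pacifica	B	52	3	(TG)_13, 22
AJ-9	A. japonica	J	54	11	(TG)_8, 9, 11, 12, 14, 15; (TG)_8AG(TG)_10
AJ-9	A. marmorata	M	56	9	(TG)_14, 15, 17, 18, 19, 23, 27
AJ-9	A. anguilla	A	54	12	(TG)_12; (TG)_10, 19, 21AG(TG)_4; (TG)_3CG(GT)_10, 11; (TG)_7CG(TG)_4AG(TG)_6
AJ-9	A. bicolor pacifica	B	54	8	(TG)_9, 10, 13, 14(AG)_1, 2(TG)_9~12; (TG)_5TA(TG)_3AG(TG)_11
AJMS-3	A. japonica	J	56	12	(TG)_7~10
AJMS-3	A. marmorata	M	56	9	(TG)_7, 9, 10
AJMS-3	A. anguilla	A	54	8	(TG)_7, 10, 11; (TG)_3, 8CG(TG)_1, 4
AJMS-3	A. bicolor pacifica	B	54	8	(TG)_7, 8, 10
AJMS-6	A. japonica	J	56	18	(TG)_9, 12~16, 18
AJMS-6	A. marmorata	M	54	12	(TG)_12, 13, 14, 16, 18, 19
AJMS-6	A. anguilla	A	54	14	(TG)_7, 10, 13, 14, 15
AJMS-6	A. bicolor pacifica	B	54	16	(TG)_12~18TA(TG)_0, 2
AJMS-10	A. japonica	J	58	12	(GA)_10, 12, 14~16, 18~22, 35, 36, 39
AJMS-10	A. marmorata	M	54	14	(GA)_8~12, 14, 15, 17
AJMS-10	A. anguilla	A	54	15	(GA)_22; (GA)_9, 12, 13, 15, 16, 17GG(GA)_6, 9, 10, 11, 12
AJMS-10	A. bicolor pacifica	B	54	19	(GA)_13~15, 17, 19, 20, 22, 23, 26; (GA)_6, 7GG(GA)_5, 12; (GA)_7CA(GA)_12, 13; (GA)_9AT(GA)_9
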