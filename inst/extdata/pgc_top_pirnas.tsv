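id	length	sequence	origin	distribution	gene	rpkm_pgc	rpkm_stagex	rpkm_gsc	rpkm_cef	fold_change
ISG_3439104	25	TATTTCCTAACGTCCAGCCTGAACC	repeat	LINE/CR1:0	NA	1147.02	13.07	13.52	0	129.42
ISG_1952422	27	CCAGAACACACTTGGCCTTCCGGGCTG	repeat	LINE/CR1:0	NA	928.3	3.78	17.55	0	130.55
ISG_2828838	25	CACTGATGGACAGGTCCTGGCTAAG	repeat	LTR/ERVL:1	NA	251.4	2.68	3.92	0	114.24
ISG_1920655	27	ACTGAACACAGCACTCGAGGTGAGGCC	repeat	LINE/CR1:0	NA	242.5	2.83	3.49	0	115.05
ISG_587310	25	TATTTCCTAACGTCCAGCCTGAATC	repeat	Ambi	NA	215.07	1.73	2.29	0	160.43
ISG_434349	27	TCCTTGCACAGCCACGACAGTCGCCTG	repeat	LINE/CR1:0	NA	205.56	0.31	3.6	0	157.61
ISG_3712010	25	TACCTGTAGAACCCCTTCTTGTTGT	repeat	LINE/CR1:0	NA	194.22	0.63	4.03	0	124.93
ISG_347271	28	TTGAACCTCATTAGGTTTTCGTGGGACC	repeat	LINE/CR1:0	NA	175.2	2.36	2.83	0	101.14
ISG_471296	27	TGCACTCGATGCCATCGTCTGTCACTG	repeat	LINE/CR1:0	NA	169.35	0.47	4.03	0	112.74
ISG_2635821	26	TTCCAGCGTTGTGTGATTTTAGAAGC	repeat	LINE/CR1:1	NA	155.45	0.63	3.16	0	123
ISG_2618644	26	TGCTGACGGACTTCCCTGGGCCTGCT	repeat	LTR/ERVL:1	NA	150.81	0.16	1.85	0	225
ISG_3554587	29	TCTGATCATCCTCTGGACTTGCTCCAAGA	repeat	LINE/CR1:0	NA	149.72	0.63	2.51	0	143.16
ISG_3050277	25	TTTTGACTTAAAAAACGTGTGCGCC	repeat	LTR/ERVL:1	NA	144.48	2.99	1.09	0	106.18
ISG_1247918	25	AAGAAAGACGCAGAGCTCTTGGACC	repeat	LINE/CR1:1	NA	130.09	0.79	3.05	0	101.63
ISG_2559548	26	TTTCCATCCCTCACTGTCTCTGAGCT	repeat	LINE/CR1:0	NA	120.94	0.16	2.07	0	162.79
ISG_2994213	27	TGTACCTGTAGAACCCCTTCTTGTTGT	repeat	LINE/CR1:0	NA	119.36	0	1.74	0	205.28
ISG_2004249	23	TTTCCTAACGTCCAGCCTGAACC	repeat	LINE/CR1:0	NA	110.95	0.16	1.64	0	185.66
ISG_988698	26	GATGATCAGAGGGCTGGAGCACCTCC	repeat	LINE/CR1:1	NA	110.22	0.63	1.96	0	127.55
ISG_1691836	26	TGTACCTGTAGAACCCCTTCTTGTTG	repeat	LINE/CR1:0	NA	109.73	0.16	1.64	0	183.61
ISG_2499527	25	AGGAATGGGCTGCCCAGAGAGGTGG	repeat	LINE/CR1:1	NA	108.39	0	1.53	0	213.04
ISG_2943457	25	GACAGACAGAGCTGCCCCTGAGCCT	intron_antisense	NM_001146136_intr_4	CHIR-B5	55.72	0	0.87	0	191.65
ISG_1259042	27	AGACTGAAGATGTGCACCTGACGCCAG	intron_sense	NM_001146141_intr_4	CHIR-AB1	49.62	0	0.76	0	195.06
ISG_2785619	26	TTCTGCATGTTGCTCTCTGTCAGCTG	intron_sense	NM_001030561_intr_5	PLLP	42.92	0	0.33	0	393.64
ISG_2237691	25	AGACTGAAGATCTGCACCTGACACC	intron_sense	NM_001146136_intr_6	CHIR-B5	35.6	0	0.87	0	122.45
ISG_2022559	27	TGTTTACTGACTGAGCTACTTTTCCCC	intron_sense	NM_205163_intr_15	MYO1A	33.41	0	0.11	0	919.25
ISG_2633063	26	AGGGTACTGAGACATCTTGGAGACAA	intron_antisense	NM_204716_intr_4	SLC6A2	19.87	0	0.33	0	182.28
ISG_1354003	21	TTTCCAAGGACCAGTAGCGCT	intron_sense	NM_205429_intr_1	17.5	18.29	0	0.55	0	100.65
ISG_2087909	26	TCTCAAAGGATTCCGCATCGTCGACG	exon_antisense	NM_001030702_exon_1	RAP2B	11.95	0	0	0	1194.81
ISG_3065006	28	AAGGACCCAAATGGTAGCAGAGGCCATG	intron_antisense	NM_205186_intr_18	LRP8	9.51	0	0.11	0	261.68
ISG_3356981	25	AATGCTGAGAACTAAGGATGCCTCC	intron_sense	NM_205098_intr_2	VDR	7.92	0	0	0	792.48
ISG_3294350	30	CAGGCTGTGACCCTGGAATTCCACTACACT	intron_sense	NM_001013397_intr_72	MYH1E	7.44	0	0.11	0	204.65
ISG_2645108	27	GAGTGTGAGAAGGGCTTTGTGCAGAGC	exon_antisense	NM_001030695_exon_5	ZNF302	5.24	0	0	0	524.26
ISG_2675670	23	CGGTGTGGGACGAGAAGGAGAAC	exon_sense	NM_204729_exon_2	RGN	4.88	0	0	0	487.68
ISG_3080707	27	CTGTGAGTGTGTGAGTGCGGCGGCGCG	intron_antisense	NM_204952_intr_1	FOXD2	4.27	0	0.11	0	117.42
ISG_3280151	24	AAGGACCTCTGAGAATTGCTTTCT	exon_sense	NM_001030884_exon_12	RASSF2	2.32	0	0	0	231.65
ISG_1621199	27	CAGAAGAGAAGCTGAACACAGGGTGTC	intron_antisense	NM_001031121_intr_7	VAMP7	1.95	0	0	0	195.07
ISG_882291	28	TTAAAGATATTTGGCTGCCTGGCTCGCC	intron_sense	NM_001081502_intr_4	NLGN1	1.95	0	0	0	195.07
ISG_2363541	26	AAGGACACCGAGGCTCTGCGTGCTGA	exon_sense	NM_205525_exon_2	APOA1	1.83	0	0	0	182.88
ISG_2033456	26	TCGGCTCGGCTCGGCTCGGCTCGGCT	exon_antisense	NM_001006501_exon_1	ADK	1.1	0	0	0	109.73
ISG_950928	27	ATCTGCGTTTAAAGCTCTTTGCACACT	intron_antisense	NM_001030561_intr_5	PLLP	1.1	0	0	0	109.73
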