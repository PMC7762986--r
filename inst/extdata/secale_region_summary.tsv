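genome	region	n_conserved	n_hypervariable	avg_pairwise	avg_pairwise_per_region	nsp	f_sp	n_shared_species	min_regions
cpDNA	atpB-rbcL	6	2	1.02	0.91	1	0.91	4	4
cpDNA	trnT-trnL	5	2	0.97	0.62	2	0.83	4	4
cpDNA	trnL-intron	4	2	0.51	0.41	4	0.87	2	1
cpDNA	trnD-trnT	4	1	0.07	0.02	3	0.72	3	2
mtDNA	nad1B-nad1C	4	1	0.06	0.01	2	0.89	2	2
mtDNA	nad4_1-2	4	2	0.27	0.23	1	0.72	2	2
mtDNA	nad4L-orf25	5	2	1.23	0.99	7	0.45	4	3
mtDNA	rps12-1_nad3-2	4	1	0.07	0.05	2	0.67	2	1
mtDNA	rps12-2_nad3-1	3	1	0.01	0.01	1	0.81	1	1
mtDNA	rrn5_rrn18-1	5	2	0.73	0.23	3	0.86	2	2
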