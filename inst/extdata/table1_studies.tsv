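study_number	host_system	sub_row	n_samples	n_taxa	n_heritable	avg_nonzero_h2	relatedness_basis	normalization	no_significance_measure	per_taxon_estimates_missing	reference_key
1	Mice	NA	32	43	NA	0.47	lineage	Total sum scaling	TRUE	FALSE	CR15
2	Chickens	NA	56	23	0	NA	pedigree	Log-transformation and scaling	FALSE	FALSE	CR16
3	Humans	winter	93	116	14	0.35	snps	Quantile normalization	FALSE	FALSE	CR17
3	Humans	summer	91	104	10	0.37	snps	Quantile normalization	FALSE	FALSE	CR17
3	Humans	combined	127	102	13	0.26	snps	Quantile normalization	FALSE	FALSE	CR17
4	Humans	NA	108	221	0	NA	twins	Box-Cox transformation	FALSE	FALSE	CR5/CR18
5	Humans	NA	126	2933	0	NA	twins	Box-Cox transformation	FALSE	FALSE	CR5/CR19
6	Humans	European ancestry	244	3	1	0.35	twins	Arcsine square root transformation	FALSE	FALSE	CR20
6	Humans	African ancestry	88	3	0	NA	twins	Arcsine square root transformation	FALSE	FALSE	CR20
7	Humans	NA	250	109	11	NA	twins	Box-Cox transformation	FALSE	TRUE	CR21
8	Humans	NA	270	249	26	0.58	pedigree	Inverse normal transformation	FALSE	FALSE	CR22
9	Switchgrass	NA	383	110	21	0.24	snps	Total sum scaling	FALSE	FALSE	CR23
10	Cows	breed 1	650	512	39	NA	snps	Quantile normalization	FALSE	TRUE	CR24
10	Cows	breed 2	200	512	3	NA	snps	Quantile normalization	FALSE	TRUE	CR24
11	Humans	NA	485	91	42	0.34	twins	Log transformation and scaling	FALSE	FALSE	CR25
12	Humans	NA	542	369	85	0.27	twins	Inverse normal transformation	FALSE	FALSE	CR26
13	Mice	NA	592	43	NA	0.51	snps	Total sum scaling	TRUE	FALSE	CR27
14	Sorghum	NA	600	1189	443	0.22	lineage	Cumulative sum scaling	FALSE	FALSE	CR28
15	Humans	NA	655	85	52	0.24	twins	Inverse normal transformation	FALSE	FALSE	CR29
16	Humans	NA	1068	21	6	0.40	snps	Box-Cox transformation	FALSE	FALSE	CR30
17	Humans	NA	1081	909	10	0.29	twins	Box-Cox transformation	FALSE	FALSE	CR5
18	Humans	NA	1176	209	11	0.31	twins	Inverse rank-sum transformation	FALSE	FALSE	CR31
19	Pigs	timepoint 1	1205	1678	170	0.056	lineage	Total sum scaling	FALSE	FALSE	CR32
19	Pigs	timepoint 2	1295	1678	261	0.078	lineage	Total sum scaling	FALSE	FALSE	CR32
19	Pigs	timepoint 3	1283	1678	366	0.099	lineage	Total sum scaling	FALSE	FALSE	CR32
20	Maize	field 2010	4866	792	143	0.17	lineage	Log transformation	FALSE	FALSE	CR33
20	Maize	field 2015	452	557	5	0.45	lineage	Log transformation	FALSE	FALSE	CR33
21	Humans	NA	326	1945	52	0.30	twins	Box-Cox transformation	FALSE	FALSE	CR6
22	Humans	NA	4745	242	31	0.20	pedigree	Centered log-ratio transformation	FALSE	FALSE	CR34
23	Baboons	NA	16234	283	273	0.068	pedigree	Total sum scaling	FALSE	FALSE	CR13
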