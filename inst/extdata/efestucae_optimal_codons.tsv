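amino_acid	codon	rscu_high	n_high	rscu_low	n_low	starred
Phe	UUU	0.41	1246	0.97	4176	FALSE
Phe	UUC	1.59	4874	1.03	4414	TRUE
Leu	UUA	0.03	86	0.54	2081	FALSE
Leu	UUG	0.55	1375	1.27	4893	FALSE
Leu	CUU	0.29	744	1.22	4713	FALSE
Leu	CUC	2.90	7320	1.10	4257	TRUE
Leu	CUA	0.14	358	0.71	2725	FALSE
Leu	CUG	2.08	5252	1.16	4456	TRUE
Ile	AUU	0.57	1339	1.20	4799	FALSE
Ile	AUC	2.24	5277	1.13	4511	TRUE
Ile	AUA	0.19	442	0.68	2704	FALSE
Met	AUG	1.00	3940	1.00	5668	FALSE
Val	GUU	0.35	1025	1.18	4457	FALSE
Val	GUC	2.39	7011	1.21	4561	TRUE
Val	GUA	0.11	322	0.63	2379	FALSE
Val	GUG	1.16	3396	0.97	3649	TRUE
Tyr	UAU	0.29	651	1.03	3182	FALSE
Tyr	UAC	1.71	3910	0.97	2979	TRUE
Ser	AGU	0.24	488	0.76	3234	FALSE
Ser	AGC	1.61	3266	1.05	4495	TRUE
His	CAU	0.42	875	1.11	3946	FALSE
His	CAC	1.58	3322	0.89	3180	TRUE
Gln	CAA	0.42	1184	1.07	6735	FALSE
Gln	CAG	1.58	4457	0.93	5867	TRUE
Asn	AAU	0.30	808	0.98	4824	FALSE
Asn	AAC	1.70	4557	1.02	4978	TRUE
Lys	AAA	0.29	1091	0.94	5763	FALSE
Lys	AAG	1.71	6306	1.06	6539	TRUE
Asp	GAU	0.40	1941	1.03	8086	FALSE
Asp	GAC	1.60	7765	0.97	7678	TRUE
Glu	GAA	0.39	1802	1.03	8278	FALSE
Glu	GAG	1.61	7396	0.97	7846	TRUE
Ser	UCU	0.40	818	1.22	5215	FALSE
Ser	UCC	1.96	3989	0.89	3811	TRUE
Ser	UCA	0.31	635	1.17	5018	FALSE
Ser	UCG	1.48	2998	0.91	3878	TRUE
Pro	CCU	0.43	1030	1.10	4937	FALSE
Pro	CCC	2.13	5100	0.81	3633	TRUE
Pro	CCA	0.32	763	1.27	5704	FALSE
Pro	CCG	1.12	2689	0.81	3651	TRUE
Thr	ACU	0.28	685	1.04	4130	FALSE
Thr	ACC	1.80	4428	0.91	3615	TRUE
Thr	ACA	0.38	941	1.20	4774	FALSE
Thr	ACG	1.54	3796	0.86	3422	TRUE
Ala	GCU	0.38	1665	1.14	6365	FALSE
Ala	GCC	2.29	9960	1.05	5840	TRUE
Ala	GCA	0.34	1462	1.10	6141	FALSE
Ala	GCG	0.99	4333	0.70	3903	TRUE
Cys	UGU	0.29	322	0.95	1626	FALSE
Cys	UGC	1.71	1869	1.05	1790	TRUE
Trp	UGG	1.00	2561	1.00	3365	FALSE
Gly	GGU	0.39	1322	0.96	4175	FALSE
Gly	GGC	2.55	8641	1.35	5864	TRUE
Gly	GGA	0.37	1263	1.03	4480	FALSE
Gly	GGG	0.69	2353	0.65	2813	FALSE
Arg	AGA	0.45	825	1.17	3566	FALSE
Arg	AGG	1.29	2390	0.79	2427	TRUE
Arg	CGU	0.37	680	0.82	2510	FALSE
Arg	CGC	2.34	4329	1.02	3113	TRUE
Arg	CGA	0.50	932	1.41	4306	FALSE
Arg	CGG	1.05	1934	0.80	2440	TRUE
Ter	UAA	0.62	101	0.79	169	FALSE
Ter	UAG	0.92	150	0.74	158	FALSE
Ter	UGA	1.47	240	1.48	317	FALSE
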