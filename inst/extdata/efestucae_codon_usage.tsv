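amino_acid	codon	count	rscu_printed
Phe	UUU	31361	0.71
Phe	UUC	53807	1.28
Leu	UUA	8539	0.22
Leu	UUG	39289	1.05
Leu	CUU	32567	0.86
Leu	CUC	63009	1.84
Leu	CUA	15908	0.42
Leu	CUG	57144	1.61
Ile	AUU	36953	0.97
Ile	AUC	56383	1.61
Ile	AUA	14980	0.42
Met	AUG	56564	1.00
Val	GUU	33011	0.83
Val	GUC	63583	1.69
Val	GUA	15230	0.39
Val	GUG	41264	1.08
Tyr	UAU	21165	0.68
Tyr	UAC	39027	1.29
Cys	UGU	10231	0.59
Cys	UGC	20393	1.25
His	CAU	27393	0.81
His	CAC	36289	1.16
Gln	CAA	44072	0.80
Gln	CAG	59569	1.19
Asn	AAU	32251	0.70
Asn	AAC	55829	1.29
Lys	AAA	37695	0.63
Lys	AAG	80172	1.37
Asp	GAU	60666	0.79
Asp	GAC	87756	1.21
Glu	GAA	60978	0.76
Glu	GAG	89320	1.23
Ser	UCU	33326	0.87
Ser	UCC	44291	1.33
Ser	UCA	30242	0.76
Ser	UCG	39274	1.14
Pro	CCU	35400	0.86
Pro	CCC	49710	1.37
Pro	CCA	35372	0.83
Pro	CCG	36167	0.93
Thr	ACU	27362	0.71
Thr	ACC	46502	1.30
Thr	ACA	31612	0.81
Thr	ACG	40791	1.17
Ala	GCU	49281	0.84
Ala	GCC	88269	1.58
Ala	GCA	44142	0.75
Ala	GCG	45406	0.83
Ter	UGA	2445	1.39
Ter	UAA	1271	0.74
Ter	UAG	1529	0.87
Trp	UGG	34101	0.94
Arg	CGU	20731	0.73
Arg	CGC	40880	1.55
Arg	CGA	33836	1.13
Arg	CGG	23806	0.86
Arg	AGA	24225	0.84
Arg	AGG	23489	0.89
Gly	GGU	35358	0.75
Gly	GGC	79015	1.79
Gly	GGA	35677	0.78
Gly	GGG	28001	0.67
Ser	AGU	21367	0.57
Ser	AGC	46172	1.32
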