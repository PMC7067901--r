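family_id	variant_id	gene_symbols	classification	protein_effect	cadd_phred	int_count	verdict
Family_1	10_88911115_AGT_A	FAM35A	Frameshift deletion	p.2_2del	25.8	2	PM2
Family_1	3_148802664_C_T	HLTF	Stopgain SNV	p.W11X	37	2	PP3 (4)
Family_1	1_177923437_CTG_C	SEC16B	Frameshift deletion	p.481_481del	36	0	Uncertain significance
Family_1	15_91546350_TG_T	VPS33B	Frameshift deletion	p.P321fs	36	3	PVS1
Family_3	7_31683260_AT_A	CCDC129	Frameshift deletion	p.D611fs	34	0	Uncertain significance
Family_3	1_21267855_C_T	EIF4G3	Stopgain SNV	p.W7X	14.54	2	PVS1, PP3 (1)
Family_3	3_188123978_G_T	LPP	Stopgain SNV	p.E24X	40	2	PM2, PP3 (4)
Family_3	15_24921469_G_A	NPAP1	Stopgain SNV	p.W152X	24.8	0	PM2, PP3 (3)
Family_3	1_241958547_CAG_C	WDR64	Frameshift deletion	p.836_836del	37	0	Uncertain significance
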