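family_id	variant_id	gene_symbols	protein_effect	cadd_phred	int_count	del_votes	verdict
Family_1	17_48746518_C_T	ABCC3	p.P652L	22.6	2	7	Uncertain significance
Family_1	1_49052793_G_A	AGBL4	p.R384C	35	2	7	Uncertain significance
Family_1	5_139909090_A_G	ANKHD1,ANKHD1-EIF4EBP3	p.N2187D	25.2	.	6	Uncertain significance
Family_1	1_160164884_T_C	CASQ1	p.I183T	26.5	2	10	Likely Benign
Family_1	14_95560456_A_C	DICER1	p.I1711M	24	3	7	Uncertain significance
Family_1	6_159206584_G_A	EZR	p.P75L	32	3	9	Uncertain significance
Family_1	12_8192537_G_A	FOXJ2	p.G37R	29.9	3	9	Uncertain significance
Family_1	14_88729713_C_T	KCNK10	p.A79T	27.1	3	6	Uncertain significance
Family_1	10_88705360_G_A	MMRN2	p.P58L	29.8	2	7	Uncertain significance
Family_1	5_36962227_G_A	NIPBL	p.R154Q	27.5	3	8	Uncertain significance
Family_1	2_206614449_A_G	NRP2	p.D596G	23.1	2	9	Uncertain significance
Family_1	1_45268632_C_T	PLK3	p.T252M	25.3	3	6	Uncertain significance
Family_1	19_45515485_T_C	RELB	p.I152T	26	3	6	Uncertain significance
Family_1	6_52372363_G_C	TRAM2	p.A205G	29.8	3	10	Uncertain significance
Family_1	22_18613830_C_T	TUBA8	p.A450V	24.7	3	10	Uncertain significance
Family_1	X_47272364_G_A	ZNF157	p.G298R	27.6	2	6	Uncertain significance
Family_2	9_116151739_G_C	ALAD	p.I243M	22.9	2	6	Uncertain significance
Family_2	9_131196759_G_T	CERCAM	p.A468S	24.5	2	7	Uncertain significance
Family_2	9_131367689_C_T	SPTAN1	p.R1327C	34	3	6	Uncertain significance
Family_3	9_139917418_C_T	ABCA2	p.G83S	26.3	2	7	Uncertain significance
Family_3	17_40971572_G_C	BECN1	p.P85R	23.4	3	6	Uncertain significance
Family_3	8_67968830_G_T	COPS5	p.P131T	23.9	3	9	Uncertain significance
Family_3	3_5246773_C_T	EDEM1	p.T160M	34	3	9	Uncertain significance
Family_3	6_131191103_G_A	EPB41L2	p.S736F	22.1	3	7	Uncertain significance
Family_3	8_28575243_G_A	EXTL3	p.R172H	23	3	6	Likely Benign
Family_3	3_188123979_A_T	LPP	p.E24V	32	2	6	Uncertain significance
Family_3	14_74970734_C_T	LTBP2	p.G1493R	27.7	3	10	Uncertain significance
Family_3	3_196730925_C_A	MFI2	p.D662Y	34	3	6	Uncertain significance
Family_3	17_27441099_G_A	MYO18A	p.A843V	24.3	3	6	Uncertain significance
Family_3	19_14584756_A_G	PTGER1	p.L126P	25.9	2	6	Uncertain significance
Family_3	3_49138083_G_A	QARS	p.R301C	34	2	9	Uncertain significance
Family_3	17_33428327_G_A	RAD51D,RAD51L3-RFFL	p.R266C	27	3	8	Benign
Family_3	11_9838541_C_T	SBF2	p.R1275H	33	2	9	Likely Benign
Family_3	9_17761502_A_G	SH3GL2	p.N14S	26.1	3	9	Uncertain significance
Family_3	20_35467682_G_A	SOGA1	p.R46C	32	3	7	Uncertain significance
Family_3	1_43891311_G_A	SZT2	p.A96T	31	3	6	Uncertain significance
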