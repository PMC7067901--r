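family_id	gene_symbols	variant_id	cadd_phred	variant_type	variant_classification	protein_effect
Family_3	ABHD16A	6_31671105_G_A	13.23	SNVs	UTR5	.
Family_3	C6orf62	6_24705773_T_C	12.31	SNVs	UTR3	.
Family_1	CEP120	5_122681069_C_T	12.31	SNVs	UTR3	.
Family_3	EDEM1	3_5246773_C_T	34	SNVs	Non-synonymous SNV	p.T160M
Family_3	EIF4G3	1_21267855_C_T	14.54	SNVs	stopgain SNV	p.W7X
Family_3	EPB41L2	6_131191103_G_A	22.1	SNVs	Non-synonymous SNV	p.S736F
Family_3	EXTL3	8_28575243_G_A	23	SNVs	Non-synonymous SNV	p.R172H
Family_1	FAM35A	10_88911115_AGT_A	25.8	Indel	Frameshift deletion	p.2_2del
Family_1	FUK	16_70501193_C_T	10.08	SNVs	UTR3	.
Family_1	HLTF	3_148802664_C_T	37	SNVs	stopgain SNV	p.W11X
Family_3	LPP	3_188608373_A_T	10.5	SNVs	UTR3	.
Family_3	LPP	3_188123978_G_T	40	SNVs	stopgain SNV	p.E24X
Family_3	LPP	3_188123979_A_T	32	SNVs	Non-synonymous SNV	p.E24V
Family_3	LRP6	12_12272924_AATATATATATATATATATATATATATATATATATATAT_A	12.55	Indel	UTR3	.
Family_3	LTBP2	14_74970734_C_T	27.7	SNVs	Non-synonymous SNV	p.G1493R
Family_3	MAPKAP1	9_128199770_TAA_T	14.3	Indel	UTR3	.
Family_3	MARCH10	17_60885673_G_A	12.03	SNVs	UTR5	.
Family_3	MYO18A	17_27441099_G_A	24.3	SNVs	Non-synonymous SNV	p.A843V
Family_1	NCAM1	11_113134920_C_A	11.07	SNVs	UTR3	.
Family_1	NIPBL	5_36962227_G_A	27.5	SNVs	Non-synonymous SNV	p.R154Q
Family_3	PHC2	1_33896663_C_A	15.12	SNVs	upstream	.
Family_3	RCN1	11_32112681_C_T	10.66	SNVs	UTR5	.
Family_3	SBF2	11_9838541_C_T	33	SNVs	Non-synonymous SNV	p.R1275H
Family_1	SLMAP	3_57742023_C_G	13.51	SNVs	UTR5	.
Family_3	SZT2	1_43891311_G_A	31	SNVs	Non-synonymous SNV	p.A96T
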