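family_id	gene_symbols	variant_id	variant_type	variant_classification	cadd_phred	category
Family_1	NCOA2	8_71316112_T_TCCTCCTCCC	Indel	Upstream	15.56	Other CancerGene
Family_1	FUBP1	1_78414225_A_G	SNVs	UTR3	13.59	Other CancerGene
Family_1	SEPT6	X_118751062_CGTGT_C	Indel	UTR3	10.56	Other CancerGene
Family_1	DICER1	14_95560456_A_C	SNVs	Non-synonymous SNV	24	Autosomal Dominant
Family_1	EZR	6_159206584_G_A	SNVs	Non-synonymous SNV	32	Other CancerGene
Family_3	BCL6	3_187463568_C_A	SNVs	Upstream; downstream	13	Other CancerGene
Family_3	LPP	3_188123978_G_T	SNVs	Stopgain SNV	40	Other CancerGene
Family_3	LPP	3_188123979_A_T	SNVs	Non-synonymous SNV	32	Other CancerGene
Family_3	LPP	3_188608373_A_T	SNVs	UTR3	10.5	Other CancerGene
Family_3	RAD51D	17_33428327_G_A	SNVs	Non-synonymous SNV	27	Other CancerGene
Family_3	PTCH1	9_98270531_C_A	SNVs	Non-synonymous SNV	20.4	Autosomal Dominant
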