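symbol	category
DICER1	Autosomal Dominant
PTCH1	Autosomal Dominant
NCOA2	Other CancerGene
FUBP1	Other CancerGene
SEPT6	Other CancerGene
EZR	Other CancerGene
BCL6	Other CancerGene
LPP	Other CancerGene
RAD51D	Other CancerGene
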