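symbol	category
ABHD16A	HL candidate
C6orf62	HL candidate
CEP120	HL candidate
EDEM1	HL candidate
EIF4G3	HL candidate
EPB41L2	HL candidate
EXTL3	HL candidate
FAM35A	HL candidate
FUK	HL candidate
HLTF	HL candidate
LPP	HL candidate
LRP6	HL candidate
LTBP2	HL candidate
MAPKAP1	HL candidate
MARCH10	HL candidate
MYO18A	HL candidate
NCAM1	HL candidate
NIPBL	HL candidate
PHC2	HL candidate
RCN1	HL candidate
SBF2	HL candidate
SLMAP	HL candidate
SZT2	HL candidate
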