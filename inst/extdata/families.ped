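Family_1	II-1	0	0	1	1
Family_1	II-2	0	0	2	2
Family_1	III-1	II-1	II-2	2	2
Family_2	II-1	0	0	2	1
Family_2	II-6	0	0	0	1	obligate_carrier
Family_2	III-1	0	0	0	1
Family_2	III-2	0	0	0	1
Family_2	III-3	0	0	0	2
Family_2	III-4	0	0	0	2
Family_2	III-5	0	0	0	2
Family_2	III-6	0	0	0	1
Family_2	III-8	0	0	0	1
Family_3	I-1	0	0	1	1	obligate_carrier
Family_3	I-2	0	0	2	1
Family_3	II-1	I-1	I-2	0	2
Family_3	II-2	I-1	I-2	0	2
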