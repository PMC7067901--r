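family_id	utr5_variants	utr3_variants
Family_1	130	347
Family_2	5	10
Family_3	314	497
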