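phenotype	genes	allelic_state	diagnosis
FH	LDLR;APOB;PCSK9;LDLRAP1	biallelic	HoFH
FH	ABCG5;ABCG8	biallelic	Sitosterolemia
any	LIPA	biallelic	LALD
FH	LDLR;APOB;PCSK9	heterozygous	HeFH
HTG	APOC2	biallelic	APOC2 deficiency
HTG	LPL;APOA5;GPIHBP1;LMF1	biallelic	Familial chylomicronemia syndrome
hypobetalipoproteinemia	MTTP	biallelic	Abetalipoproteinemia
hypobetalipoproteinemia	APOB	biallelic	Homozygous FHBL
hypobetalipoproteinemia	SAR1B	biallelic	Chylomicron retention disease
hypoalphalipoproteinemia	LCAT	biallelic	LCAT deficiency
hypoalphalipoproteinemia	APOA1	biallelic	Apo A-I deficiency
hypoalphalipoproteinemia	ABCA1	biallelic	Tangier disease
lipodystrophy	LMNA	heterozygous	FPLD2
lipodystrophy	PPARG	heterozygous	FPLD3
MODY	HNF1A	heterozygous	MODY3
MODY	GCK	heterozygous	MODY2
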