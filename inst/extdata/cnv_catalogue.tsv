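gene	region	state	breakpoint_tag	instances
ABCA1	5'UTR - 3'UTR	het_deletion		1
ABCA1	Exons 47-48	het_deletion		1
ABCA1	Exons 8-31	het_deletion		2
ABCA1	Exons 4-7	duplication		1
ABCA1	Exon 4	het_deletion		1
ABCG1	Non-coding exon 1 - 3'UTR	duplication		2
ABCG8	Exons 4-6	duplication		3
AGPAT2	Exons 2-4	het_deletion		1
AGPAT2	5'UTR - Exon 1	het_deletion		1
ANGPTL3	Exon 3 - 3'UTR	het_deletion		1
APOA5	5'UTR - 3'UTR	het_deletion		1
APOA5 and APOA4	5'UTR - 3'UTR, 5'UTR - 3'UTR	duplication		1
APOB	5'UTR - 3'UTR	duplication		1
APOC2	Non-coding exon 1	hom_deletion		1
BLK	Exon 2 - 3'UTR	duplication		29
BLK	Exon 10	duplication		1
CAV2	5'UTR - Exon 1	duplication		1
CETP	5'UTR - Exon 2	het_deletion		1
CIDEC	Exon 4 - 3'UTR	het_deletion		1
CIDEC	Alternative non-coding exon 1a	het_deletion		3
CREB3L3	5'UTR - Exon 2	het_deletion		1
CREB3L3	5'UTR - 3'UTR	duplication		2
CREB3L3	Exons 3-4	het_deletion		1
CREB3L3	Exon 5	het_deletion		1
GCK	5'UTR - Alternative exon 1	het_deletion		5
GCK	5'UTR - Alternative exon 1	duplication		1
GPIHBP1	5'UTR - 3'UTR	hom_deletion		3
GPIHBP1	Exons 3-4	het_deletion		3
HNF1B	5'UTR - 3'UTR	het_deletion		3
HNF4A	5'UTR - Exon 1	het_deletion		1
HNF4A	5'UTR - 3'UTR	het_deletion		1
LDLR	5'UTR - Exon 1	het_deletion		1
LDLR	5'UTR - Intron 1	het_deletion		33
LDLR	5'UTR - Exon 2	het_deletion		3
LDLR	5'UTR - Exon 6	het_deletion		1
LDLR	Exons 2-3	het_deletion		1
LDLR	Exons 2-6	duplication		1
LDLR	Exons 2-6	het_deletion		10
LDLR	Exons 3-6	het_deletion		4
LDLR	Exons 4-6	het_deletion		1
LDLR	Exons 5-6	het_deletion		1
LDLR	Exon 7	duplication		1
LDLR	Exons 9-10	het_deletion		1
LDLR	Exons 11-12	duplication	a	1
LDLR	Exons 11-12	duplication	b	1
LDLR	Exons 11-12	het_deletion		1
LDLR	Exons 13-14	het_deletion		1
LDLR	Exons 13-15	het_deletion		1
LDLR	Exon 16 - 3'UTR	het_deletion		1
LDLR	Exon 17 - 3'UTR	het_deletion		5
LDLR	Exons 18 - 3'UTR	het_deletion		1
LDLRAP1	5'UTR - Exon 1	duplication		1
LIPA	Exon 9 - 3'UTR	het_deletion		1
LIPA	Exon 4	het_deletion		2
LIPC	5'UTR - Exon 1	het_deletion		6
LMF1	Exon 6	het_deletion		2
LPIN1	Exons 2-4	het_deletion		1
LPIN1	Alternative exon 6	het_deletion		1
LPIN1	Exon 18	het_deletion		3
LPIN1	Exons 18-19	het_deletion		1
LPL	5'UTR - Exon 1	het_deletion		1
LPL	5'UTR - Exon 2	het_deletion		3
MFN2	Exons 4-6	duplication		1
MTTP	5'UTR - 3'UTR	het_deletion		1
MTTP	Exon 10	het_deletion		1
MTTP	Exons 10-15	hom_deletion		2
MTTP	Exons 10-15	het_deletion		1
NPC1L1	Exons 6-10	het_deletion		1
PCSK9	5'UTR - 3'UTR	duplication		5
PLIN1	Exon 3 - 3'UTR	duplication		1
PLIN1	Exon 8	het_deletion		2
PLIN1	Exon 2	het_deletion		1
PNPLA2	5'UTR - 3'UTR	duplication		1
POLD1	5'UTR	duplication		2
PPARA	Alternative non-coding exon 1 - 3'UTR	duplication		1
WRN	Exon 3	het_deletion		1
WRN	Exons 9-11	het_deletion		1
WRN	Exon 10	duplication		1
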