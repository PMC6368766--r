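rank	symbol	status	comparison_symbol
1	BRCA2	YES+Seed	TNF
2	ESR1	YES+Seed	EGFR
3	CDH1	YES+Seed	CRC
4	BRCA1	YES	PTEN
5	PPM1D	YES+Seed	IL-6
6	NQO2	YES+Seed	AR
7	XRCC3	YES+Seed	BRCA1
8	TSG101	YES+Seed	EGF
9	CDKN2A	candidate	GAPDH
10	PALB2	YES+Seed	HR
11	BRIP1	YES+Seed	AML
12	PIK3CA	YES+Seed	CD4
13	MRE11A	candidate	STAT3
14	RAD54L	YES+Seed	AD
15	ERBB2	YES	MMP-9
16	CHEK2	YES+Seed	MS
17	RAD51C	candidate	RD
18	AKT1	YES+Seed	MYC
19	TP53	YES+Seed	S6
20	RB1CC1	YES+Seed	TP53
21	RB1	YES	ATM
22	HMMR	YES+Seed	IL-8
23	STK11	YES	AP1
24	BARD1	YES+Seed	MMP-2
25	RAD51	YES	GC
26	KRAS	YES+Seed	FBS
27	RAD50	candidate	ES
28	ATM	YES+Seed	RAB
29	ACH1	Seed	CXCR4
30	CASP8	YES+Seed	BRCA2
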