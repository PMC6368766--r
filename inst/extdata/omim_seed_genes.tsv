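disease	symbol
prostate	PCAP
prostate	HPC5
prostate	MAD1L1
prostate	HPC4
prostate	HIP1
prostate	MSR1
prostate	KLF6
prostate	PTEN
prostate	MXI1
prostate	CD82
prostate	BRCA2
prostate	CDH1
prostate	ZFHX3
prostate	HPCQTL19
prostate	HPC3
prostate	CHEK2
prostate	HPC6
prostate	AR
breast	RAD54L
breast	CASP8
breast	BARD1
breast	PIK3CA
breast	HMMR
breast	NQO2
breast	ESR1
breast	RB1CC1
breast	SLC22A1L
breast	TSG101
breast	ATM
breast	KRAS
breast	BRCA2
breast	XRCC3
breast	AKT1
breast	RAD51A
breast	PALB2
breast	CDH1
breast	TP53
breast	PHB
breast	PPM1D
breast	BRIP1
breast	CHEK2
lung	FASLG
lung	CASP8
lung	DLEC1
lung	RASSF1
lung	PIK3CA
lung	IRF1
lung	PRKN
lung	EGFR
lung	BRAF
lung	MAP3K8
lung	ERCC6
lung	SLC22A1L
lung	PPP2R1B
lung	KRAS
lung	ERBB2
lung	CYP2A6
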