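set_name	gene
glycolysis	GPI
glycolysis	ENO1
glycolysis	HK1
glycolysis	LDHA
glycolysis	LDHB
glycolysis	PFKL
glycolysis	PKM
glycolysis	ALDOA
glycolysis	GAPDH
glycolysis	PGK1
oxphos	IDH1
oxphos	IDH2
oxphos	CS
oxphos	SDHA
oxphos	FH
oxphos	MDH2
oxphos	NDUFS1
oxphos	COX5A
oxphos	UQCRC1
oxphos	ATP5F1A
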