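ligand	receptor
TGFB1	TGFBR1
TGFB1	TGFBR2
PDGFB	PDGFRB
PDGFA	PDGFRA
CTGF	LRP6
EGF	EGFR
HGF	MET
VEGFA	FLT1
VEGFA	KDR
FGF2	FGFR1
WNT4	FZD1
JAG1	NOTCH3
DLL4	NOTCH1
CCL2	CCR2
TNF	TNFRSF1A
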