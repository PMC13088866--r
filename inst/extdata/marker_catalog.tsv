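type	gene
PT	SLC34A1
PT	SLC5A2
PT	LRP2
PT	CUBN
PT	ALDOB
PT	GATM
Endo	PECAM1
Endo	FLT1
Endo	KDR
Endo	EMCN
Endo	CDH5
Fib	COL1A1
Fib	COL1A2
Fib	PDGFRA
Fib	DCN
Fib	LUM
Peri	PDGFRB
Peri	RGS5
Peri	NOTCH3
Peri	MYH11
Peri	ACTA2
Podo	NPHS1
Podo	NPHS2
Podo	PODXL
Podo	WT1
Podo	SYNPO
Mac	CD68
Mac	CD14
Mac	CSF1R
Mac	LYZ
Mac	ITGAM
TC	CD3E
TC	CD3D
TC	CD2
TC	IL7R
TC	TRAC
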