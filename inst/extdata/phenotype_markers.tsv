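phenotype	gene
T_eff	GZMB
T_eff	PRF1
T_eff	KLRG1
T_eff	CX3CR1
T_em	GZMK
T_em	CCL5
T_em	NKG7
T_em	CST7
T_cm	CCR7
T_cm	SELL
T_cm	CD27
T_cm	GPR183
T_scm	TCF7
T_scm	LEF1
T_scm	CD28
T_scm	FAS
naive	IL7R
naive	LTB
naive	SATB1
naive	TXK
Th1	TBX21
Th1	CXCR3
Th1	IL12RB2
Th1	STAT4
Th2	GATA3
Th2	CCR4
Th2	IL4R
Th2	STAT6
Th17	RORC
Th17	CCR6
Th17	IL23R
Th17	IL17RA
T_reg	FOXP3
T_reg	IL2RA
T_reg	IKZF2
T_reg	TNFRSF18
T_eff	FGFBP2
T_eff	GNLY
T_em	GZMA
T_em	KLRD1
T_cm	AQP3
T_cm	ICAM2
T_scm	BACH2
T_scm	IL6ST
naive	NOSIP
naive	PIK3IP1
Th1	IL18R1
Th1	STAT1
Th2	IL17RB
Th2	PTGDR2
Th17	KLRB1
Th17	CCL20
T_reg	CCR8
T_reg	LAYN
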