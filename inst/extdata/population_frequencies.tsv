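source	n_individuals	gene_symbol	allele_name	freq_percent
ThisStudy	205	BCAM	LU*02	100
ThisStudy	205	BCAM	LU*01	0
ThisStudy	205	KEL	KEL*02	100
ThisStudy	205	KEL	KEL*01.01	0
ThisStudy	205	ACKR1	FY*02	3.91
ThisStudy	205	ACKR1	FY*01	93.02
ThisStudy	205	ACKR1	FY*01.1000G	3.07
ThisStudy	205	SLC4A1	DI*02	100
ThisStudy	205	SLC4A1	DI*01	0
ThisStudy	205	ACHE	YT*01	100
ThisStudy	205	ACHE	YT*02	0
ThisStudy	205	XG	XG*01	100
ThisStudy	205	ERMAP	SC*01	96.09
ThisStudy	205	ERMAP	SC*02	0.28
ThisStudy	205	ERMAP	SC*1000G.835A	0.28
ThisStudy	205	ERMAP	SC*1000G.976G	3.35
ThisStudy	205	ART4	DO*01	3.35
ThisStudy	205	ART4	DO*02	96.37
ThisStudy	205	AQP1	CO*01.01	100
ThisStudy	205	AQP1	CO*02	0
ThisStudy	205	ICAM4	LW*05	100
ThisStudy	205	C4A	C4A*3	100
ThisStudy	205	C4B	C4B*3	100
ThisStudy	205	FUT1	FUT1*01	91.62
ThisStudy	205	FUT1	FUT1*02	7.82
ThisStudy	205	XK	XK*01	100
ThisStudy	205	GYPC	GE*01	100
ThisStudy	205	CD55	CROM*01	100
ThisStudy	205	CD44	IN*02	100
ThisStudy	205	BSG	OK*01.01	100
ThisStudy	205	CD151	RAPH*01	100
ThisStudy	205	SEMA7A	JMH*01	100
ThisStudy	205	GBGT1	GBGT1*01N.01	94.14
ThisStudy	205	GBGT1	GBGT1*1000G.397A	1.95
ThisStudy	205	GBGT1	GBGT1*1000G.707A	2.93
ThisStudy	205	GBGT1	GBGT1*1000G.728A	0.98
ThisStudy	205	ABCG2	ABCG2*1000G.34A	2.44
ThisStudy	205	ABCG2	ABCG2*1000G.167A	0.49
ThisStudy	205	SMIM1	VEL*01	100
ThisStudy	205	KLF1	KLF1*01	73.66
ThisStudy	205	KLF1	KLF1*BGM12	22.93
ThisStudy	205	KLF1	KLF1*1000G.325T	1.95
ThisStudy	205	KLF1	KLF1*1000G.304C.544C	0.98
KRBP	419	BCAM	LU*02	99.39
KRBP	419	BCAM	LU*01	0.61
KRBP	419	KEL	KEL*02	100
KRBP	419	KEL	KEL*01.01	0
KRBP	419	ACKR1	FY*02	8.95
KRBP	419	ACKR1	FY*01	91.05
KRBP	419	SLC4A1	DI*02	93.08
KRBP	419	SLC4A1	DI*01	6.92
KRBP	419	ACHE	YT*01	99.88
KRBP	419	ACHE	YT*02	0.12
KRBP	419	ERMAP	SC*01	100
KRBP	419	ERMAP	SC*02	0
KRBP	419	ART4	DO*01	10.14
KRBP	419	ART4	DO*02	89.86
KRBP	419	ICAM4	LW*05	100
KRBP	419	CD55	CROM*01	100
ErythrogeneEastAsia	504	BCAM	LU*02	84.82
ErythrogeneEastAsia	504	BCAM	LU*01	0
ErythrogeneEastAsia	504	KEL	KEL*02	63.79
ErythrogeneEastAsia	504	KEL	KEL*01.01	0
ErythrogeneEastAsia	504	ACKR1	FY*02	7.74
ErythrogeneEastAsia	504	ACKR1	FY*01	83.23
ErythrogeneEastAsia	504	ACKR1	FY*01.1000G	8.73
ErythrogeneEastAsia	504	SLC4A1	DI*02	78.57
ErythrogeneEastAsia	504	SLC4A1	DI*01	0.30
ErythrogeneEastAsia	504	ACHE	YT*01	86.31
ErythrogeneEastAsia	504	ACHE	YT*02	0.20
ErythrogeneEastAsia	504	XG	XG*01	99.87
ErythrogeneEastAsia	504	ERMAP	SC*01	93.75
ErythrogeneEastAsia	504	ERMAP	SC*02	0
ErythrogeneEastAsia	504	ERMAP	SC*1000G.835A	1.19
ErythrogeneEastAsia	504	ERMAP	SC*1000G.976G	1.79
ErythrogeneEastAsia	504	ART4	DO*01	9.42
ErythrogeneEastAsia	504	ART4	DO*02	82.54
ErythrogeneEastAsia	504	AQP1	CO*01.01	99.01
ErythrogeneEastAsia	504	AQP1	CO*02	0
ErythrogeneEastAsia	504	ICAM4	LW*05	99.70
ErythrogeneEastAsia	504	C4A	C4A*3	30.26
ErythrogeneEastAsia	504	C4B	C4B*3	99.40
ErythrogeneEastAsia	504	FUT1	FUT1*01	67.66
ErythrogeneEastAsia	504	FUT1	FUT1*02	31.25
ErythrogeneEastAsia	504	XK	XK*01	100
ErythrogeneEastAsia	504	GYPC	GE*01	99.50
ErythrogeneEastAsia	504	CD55	CROM*01	99.60
ErythrogeneEastAsia	504	CD44	IN*02	99.80
ErythrogeneEastAsia	504	BSG	OK*01.01	97.62
ErythrogeneEastAsia	504	CD151	RAPH*01	98.91
ErythrogeneEastAsia	504	SEMA7A	JMH*01	99.11
ErythrogeneEastAsia	504	GBGT1	GBGT1*01N.01	45.44
ErythrogeneEastAsia	504	GBGT1	GBGT1*1000G.397A	0.20
ErythrogeneEastAsia	504	GBGT1	GBGT1*1000G.707A	0.50
ErythrogeneEastAsia	504	GBGT1	GBGT1*1000G.728A	0.30
ErythrogeneEastAsia	504	ABCG2	ABCG2*1000G.34A	29.66
ErythrogeneEastAsia	504	ABCG2	ABCG2*1000G.167A	0
ErythrogeneEastAsia	504	SMIM1	VEL*01	99.90
ErythrogeneEastAsia	504	KLF1	KLF1*01	30.75
ErythrogeneEastAsia	504	KLF1	KLF1*BGM12	59.23
ErythrogeneEastAsia	504	KLF1	KLF1*1000G.325T	7.64
ErythrogeneEastAsia	504	KLF1	KLF1*1000G.304C.544C	1.69
ErythrogeneAll	2504	BCAM	LU*02	66.77
ErythrogeneAll	2504	BCAM	LU*01	0.22
ErythrogeneAll	2504	KEL	KEL*02	65.93
ErythrogeneAll	2504	KEL	KEL*01.01	1.12
ErythrogeneAll	2504	ACKR1	FY*02	20.51
ErythrogeneAll	2504	ACKR1	FY*01	43.65
ErythrogeneAll	2504	ACKR1	FY*01.1000G	2.16
ErythrogeneAll	2504	SLC4A1	DI*02	83.85
ErythrogeneAll	2504	SLC4A1	DI*01	0.18
ErythrogeneAll	2504	ACHE	YT*01	68.77
ErythrogeneAll	2504	ACHE	YT*02	2.46
ErythrogeneAll	2504	XG	XG*01	95.60
ErythrogeneAll	2504	ERMAP	SC*01	81.07
ErythrogeneAll	2504	ERMAP	SC*02	0.06
ErythrogeneAll	2504	ERMAP	SC*1000G.835A	0.26
ErythrogeneAll	2504	ERMAP	SC*1000G.976G	0.66
ErythrogeneAll	2504	ART4	DO*01	25.10
ErythrogeneAll	2504	ART4	DO*02	59.37
ErythrogeneAll	2504	AQP1	CO*01.01	95.61
ErythrogeneAll	2504	AQP1	CO*02	1.14
ErythrogeneAll	2504	ICAM4	LW*05	98.96
ErythrogeneAll	2504	C4A	C4A*3	30.93
ErythrogeneAll	2504	C4B	C4B*3	99.50
ErythrogeneAll	2504	FUT1	FUT1*01	89.22
ErythrogeneAll	2504	FUT1	FUT1*02	9.82
ErythrogeneAll	2504	XK	XK*01	99.92
ErythrogeneAll	2504	GYPC	GE*01	97.40
ErythrogeneAll	2504	CD55	CROM*01	97.72
ErythrogeneAll	2504	CD44	IN*02	99.04
ErythrogeneAll	2504	BSG	OK*01.01	98.20
ErythrogeneAll	2504	CD151	RAPH*01	98.94
ErythrogeneAll	2504	SEMA7A	JMH*01	96.37
ErythrogeneAll	2504	GBGT1	GBGT1*01N.01	59.96
ErythrogeneAll	2504	GBGT1	GBGT1*1000G.397A	0.04
ErythrogeneAll	2504	GBGT1	GBGT1*1000G.707A	0.12
ErythrogeneAll	2504	GBGT1	GBGT1*1000G.728A	0.10
ErythrogeneAll	2504	ABCG2	ABCG2*1000G.34A	13.68
ErythrogeneAll	2504	ABCG2	ABCG2*1000G.167A	0.02
ErythrogeneAll	2504	SMIM1	VEL*01	99.96
ErythrogeneAll	2504	KLF1	KLF1*01	53.53
ErythrogeneAll	2504	KLF1	KLF1*BGM12	37.88
ErythrogeneAll	2504	KLF1	KLF1*1000G.325T	1.54
ErythrogeneAll	2504	KLF1	KLF1*1000G.304C.544C	4.89
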