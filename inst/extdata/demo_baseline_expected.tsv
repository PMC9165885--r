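gene_symbol	conventional_allele	hgvs_c	hgvs_p	predicted_allele
GYPA	GYPA*01	38C>A;59C>T;71_72delGTinsAG;93C>T	Ala13Glu;Ser20Leu;Gly24Glu	ND
RHD	RHD*01	1136C>T	Thr379Met	RHD*DAU0
RHCE	RHCE*01	48G>C	Trp16Cys	RHCE*01.01
FUT3	FUT3*01	202T>C;314C>T	Trp68Arg;Thr105Met	ND
ACKR1	FY*02	125A>G	Asp42Gly	FY*01
SLC14A1	JK*02	838A>G	Asn280Asp	JK*01
ART4	DO*01	378C>T;624T>C;793A>G	Asn265Asp	DO*02
CR1	KN*01	180G>A;4828T>A;5905G>A	Ser1610Thr;Ala1969Thr	ND
GCNT2	GCNT2*01	816G>C	Glu272Asp	GCNT2*02
BCAM	LU*02	-	-	LU*02
KEL	KEL*02	-	-	KEL*02
ICAM4	LW*05	-	-	LW*05
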