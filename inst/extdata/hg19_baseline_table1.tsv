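isbt_no	system	gene_symbol	chromosomal_location	conventional_allele	conventional_phenotype	nucleotide_changes	amino_acid_changes	predicted_allele
001	ABO	ABO	9q34.2	ABO*A1.01	A1	-	-	ABO*A1.01
002	MNS	GYPA	4q31.21	GYPA*01	M+	38C>A; 59C>T; 71G>A; 72T>G; 93C>T	Ala13Glu; Ser20Leu; Gly24Glu	ND
002	MNS	GYPB	4q31.21	GYPB*04	s+	-	-	GYPB*04
003	P1PK	A4GALT	22q13.2	A4GALT*01	P1+/- Pk+	-	-	A4GALT*01
004	Rh	RHD	1p36.11	RHD*01	D	1136C>T	Thr379Met	RHD*10.00 RHD*DAU0
004	Rh	RHCE	1p36.11	RHCE*01	c+e+	48G>C	Trp16Cys	RHCE*01.01
005	Lutheran	BCAM	19q13.32	LU*02	Lu(b+)	-	-	LU*02
006	Kell	KEL	7q34	KEL*02	k+	-	-	KEL*02
007	Lewis	FUT3	19p13.3	FUT3	ND	202T>C; 314C>T	Trp68Arg; Thr105Met	FUT3 202C, 314T
008	Duffy	ACKR1	1q23.2	FY*02	Fy(b+)	125A>G	Asp42Gly	FY*01
009	Kidd	SLC14A1	18q12.3	JK*02	Jk(b+)	838A>G	Asn280Asp	JK*01
010	Diego	SLC4A1	17q21.31	DI*02	Di(a-b+)	-	-	DI*02
011	Yt	ACHE	7q22.1	YT*01	Yt(a+)	-	-	YT*01
012	Xg	XG	Xp22.33	XG*01	Xg(a+)	-	-	XG*01
013	Scianna	ERMAP	1p34.2	SC*01	Sc1+	-	-	SC*01
014	Dombrock	ART4	12p12.3	DO*01	Do(a+)	378C>T; 624T>C; 793A>G	Asn265Asp	DO*02
015	Colton	AQP1	7p14.3	CO*01.01	Co(a+)	-	-	CO*01.01
016	Landsteiner-Wiener	ICAM4	19p13.2	LW*05	LW(a+)	-	-	LW*05
017	Chido/Rodgers	C4A	6p21.33	C4A*3	Ch-Rg+	-	-	C4A*3
017	Chido/Rodgers	C4B	6p21.33	C4B*3	Ch+Rg-	-	-	C4B*3
018	H	FUT1	19q13.33	FUT1*01	H+	-	-	FUT1*01
018	H	FUT2	19q13.33	FUT2*01	H+	-	-	FUT2*01
019	Kx	XK	Xp21.1	XK*01	Kx+	-	-	XK*01
020	Gerbich	GYPC	2q14.3	GE*01	GE:2,3,4	-	-	GE*01
021	Cromer	CD55	1q32.2	CROM*01	Cr(a+)	-	-	CROM*01
022	Knops	CR1	1q32.2	KN*01	KN:1,3,4,8,9	180G>A; 4828T>A; 5905G>A	Ser1610Thr; Ala1969Thr	ND
023	Indian	CD44	11p13	IN*02	In(a-b+)	-	-	IN*02
024	Ok	BSG	19p13.3	OK*01.01	Ok(a+)	-	-	OK*01.01
025	Raph	CD151	11p15.5	RAPH*01	MER2+	-	-	RAPH*01
026	John Milton Hagen	SEMA7A	15q24.1	JMH*01	JMH+	-	-	JMH*01
027	I	GCNT2	6p24.3-p24.2	GCNT2*01	I	816G>C	Glu272Asp	GCNT2*02
028	Globoside	B3GALNT1	3q26.1	GLOB*01	P+	-	-	GLOB*01
029	Gill	AQP3	9p13.3	GIL*01	GIL+	-	-	GIL*01
030	Rh-associated glycoprotein	RHAG	6p12.3	RHAG*01	Duclos+	-	-	RHAG*01
031	FORS	GBGT1	9q34.2	GBGT1*01N.01	FORS-	-	-	GBGT1*01N.01
032	JR	ABCG2	4q22.1	ABCG2*01	Jr(a+)	-	-	ABCG2*01
033	LAN	ABCB6	2q35	ABCB6*01	Lan+	-	-	ABCB6*01
034	Vel	SMIM1	1p36.32	VEL*01	Vel+	-	-	VEL*01
035	CD59	CD59	11p13	CD59*01	CD59.1+	-	-	CD59*01
036	Augustine	SLC29A1	6p21.1	AUG*01	At(a+)	-	-	AUG*01
NA	Associated	GATA1	Xp11.23	GATA1*01	-	-	-	GATA1*01
NA	Associated	KLF1	19p13.13	KLF1*01	-	-	-	KLF1*01
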