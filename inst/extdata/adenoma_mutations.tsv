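case	chrom	pos	ref	alt	gene	protein_change	consequence	regions
MSS1	chr5	112175100	AT	A	APC	p.E1554fs	frameshift_indel	T1,T2,T3
MSS1	chr12	46123600	CA	C	ARID2	p.K15fs	frameshift_indel	T1,T2
MSS1	chr19	11144020	C	T	SMARCA4	p.R1157W	missense	T1
MSS1	chr19	11132250	C	T	SMARCA4	p.T910M	missense	T2
MSS1	chr17	37881000	G	A	ERBB2	p.V842I	missense	T1,T2
MSS2	chr5	112162400	CT	C	APC	p.S1110fs	frameshift_indel	T1,T2,T3
MSS2	chr5	112174630	C	T	APC	p.R1450X	nonsense	T1,T2,T3
MSS2	chr12	46230100	C	T	ARID2	p.Q995X	nonsense	T1
MSS2	chr12	46160500	G	T	ARID2	p.E376X	nonsense	T2
MSS2	chr3	52600900	C	T	PBRM1	p.R710X	nonsense	T1,T2
MSS2	chr12	25398281	C	T	KRAS	p.G13D	missense	T3
MSS2	chr4	153258100	C	T	FBXW7	p.R505X	nonsense	T1
MSS2	chr4	153249385	G	A	FBXW7	p.R465C	missense	T2
MSS3	chr5	112175100	AT	A	APC	p.E1554fs	frameshift_indel	T1,T2,T3
MSS3	chr5	112111400	C	T	APC	p.Q480X	nonsense	T1
MSS3	chr12	46190300	C	T	ARID2	p.Q480X	nonsense	T1
MSS3	chr12	46245800	G	A	ARID2		splicing	T2
MSS3	chr17	7577120	G	A	TP53	p.R273C	missense	T1,T2
MSS3	chr11	108205710	G	A	ATM	p.R2443Q	missense	T3
MSI-H1	chr5	112090560	C	T	APC	p.R215X	nonsense	T1,T2,T3
MSI-H1	chr5	112174640	GA	G	APC	p.K1452fs	frameshift_indel	T1,T2,T3
MSI-H1	chr19	15360200	CT	C	BRD4	p.P1000fs	frameshift_indel	T1
MSI-H1	chr12	49425900	GA	G	KMT2D	p.Q2800fs	frameshift_indel	T2
MSI-H1	chr1	147080300	TA	T	BCL9	p.M1400fs	frameshift_indel	T1,T2,T3
MSI-H1	chr2	202131200	CT	C	CASP8	p.K252fs	frameshift_indel	T1,T2,T3
MSI-H1	chr16	27440100	GA	G	IL21R	p.T305fs	frameshift_indel	T1,T2,T3
MSI-H1	chr5	56177300	CA	C	MAP3K1	p.N910fs	frameshift_indel	T1,T2,T3
MSI-H1	chr8	103289500	AT	A	UBR5	p.S2110fs	frameshift_indel	T1,T2,T3
MSI-H2	chr5	112174630	C	T	APC	p.R1450X	nonsense	T1,T2,T3
MSI-H2	chr5	112064200	TC	T	APC	p.Y158fs	frameshift_indel	T1,T2,T3
MSI-H2	chr19	11144020	C	T	SMARCA4	p.R1157W	missense	T1,T2,T3
MSI-H2	chr19	11132250	C	T	SMARCA4	p.T910M	missense	T1,T2,T3
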