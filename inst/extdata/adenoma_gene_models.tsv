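chrom	start	end	gene
chr1	147013181	147098016	BCL9
chr2	202098165	202152434	CASP8
chr3	52579367	52719933	PBRM1
chr4	153242409	153457253	FBXW7
chr5	56111400	56191979	MAP3K1
chr5	112043194	112181936	APC
chr8	103265623	103425122	UBR5
chr11	108093210	108239829	ATM
chr12	25358179	25403854	KRAS
chr12	46123447	46301823	ARID2
chr12	49412757	49453557	KMT2D
chr16	27413482	27462313	IL21R
chr17	7571719	7590868	TP53
chr17	37844166	37886679	ERBB2
chr19	11071597	11176958	SMARCA4
chr19	15348596	15391875	BRD4
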