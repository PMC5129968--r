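case	region	chrom	start	end	n_bins	mean_log2
MSS1	T1	chr5	111500000	112800000	55	-0.52
MSS1	T2	chr5	111500000	112800000	55	-0.49
MSS1	T3	chr5	111500000	112800000	55	-0.51
MSS3	T2	chr5	48400000	180915260	2100	-0.47
MSS3	T3	chr5	111500000	112800000	55	-0.50
MSS3	T3	chr12	35800000	133851895	1650	-0.41
MSI-H1	T1	chr8	46000000	146364022	1700	0.42
MSI-H1	T2	chr8	46000000	146364022	1700	0.40
MSI-H1	T3	chr8	46000000	146364022	1700	0.44
MSI-H2	T1	chr6	10000000	20000000	110	-0.52
MSI-H2	T1	chr6	20000000	30000000	105	0.41
MSI-H2	T1	chr6	30000000	40000000	108	-0.49
MSI-H2	T1	chr6	40000000	50000000	112	0.39
MSI-H2	T1	chr6	50000000	60000000	104	-0.51
MSI-H2	T1	chr6	62000000	72000000	102	0.42
MSI-H2	T1	chr6	72000000	82000000	101	-0.50
MSI-H2	T1	chr6	82000000	92000000	103	0.40
MSI-H2	T2	chr6	10000000	20000000	110	-0.50
MSI-H2	T2	chr6	20000000	30000000	105	0.40
MSI-H2	T2	chr6	30000000	40000000	108	-0.52
MSI-H2	T2	chr6	40000000	50000000	112	0.41
MSI-H2	T2	chr6	50000000	60000000	104	-0.48
MSI-H2	T2	chr6	62000000	72000000	102	0.40
MSI-H2	T2	chr6	72000000	82000000	101	-0.51
MSI-H2	T2	chr6	82000000	92000000	103	0.42
MSI-H2	T3	chr6	10000000	20000000	110	-0.51
MSI-H2	T3	chr6	20000000	30000000	105	0.42
MSI-H2	T3	chr6	30000000	40000000	108	-0.50
MSI-H2	T3	chr6	40000000	50000000	112	0.40
MSI-H2	T3	chr6	50000000	60000000	104	-0.49
MSI-H2	T3	chr6	62000000	72000000	102	0.41
MSI-H2	T3	chr6	72000000	82000000	101	-0.52
MSI-H2	T3	chr6	82000000	92000000	103	0.41
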