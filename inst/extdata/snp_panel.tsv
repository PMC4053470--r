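snp_id	chr	gene	model	beta	se	p	power_pct	maf_synthetic
rs174611	11	FADS2	ADD	0.1759	0.05069	0.0005402	94.62	0.30
rs174577	11	FADS2	ADD	0.1755	0.04799	0.0002677	96.23	0.35
rs174616	11	FADS2	ADD	0.0904	0.04436	0.04177	54.32	0.40
rs174546	11	FADS1	ADD	0.1562	0.04914	0.001526	89.84	0.32
rs511895	11	CAT	ADD	-0.1369	0.04774	0.00421	84.77	0.35
rs662799	11	APOA5	ADD	0.2792	0.0952	0.003431	82.39	0.12
rs651821	11	APOC3_APOA1_APOA4	DOM	0.2649	0.09611	0.005952	77.78	0.12
rs3759347	12	GNB3_LEPREL2	ADD	0.1643	0.0493	0.0008897	92.89	0.33
rs10492025	12	RPH3A	ADD	0.1411	0.04879	0.003906	84.73	0.28
rs1129649	12	GNB3	ADD	0.1246	0.04766	0.009086	76.98	0.36
rs1566441	16	BBS2_MT4	ADD	-0.1302	0.04611	0.004825	84.11	0.38
rs11644094	16	MT3	REC	0.1121	0.04535	0.01365	72.27	0.40
rs8044769	16	FTO	DOM	-0.1306	0.04505	0.003821	84.66	0.45
rs4359	17	ACE	ADD	-0.1316	0.04679	0.004994	83.51	0.35
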