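SNP	risk_allele	other_allele	freq	published_OR	gene	chrom	bp
chr1:154105678	T	C	0.13	1.44	SYT11	1	154105678
rs708723	C	T	0.40	0.86	RAB7L1	1	204005889
rs2102808	T	G	0.12	1.12	STK39	2	168825271
rs34016896	T	C	0.33	1.08	NMD3	3	162475558
rs11711441	A	G	0.12	0.87	MCCC1	3	184303969
rs11724635	C	A	0.41	0.87	BST1	4	15346199
rs6812193	T	C	0.33	0.91	STBD1	4	77418010
rs356219	G	A	0.41	1.27	SNCA	4	90856624
rs156429	C	T	0.37	0.89	GPNMB	7	23272545
rs591323	A	G	0.33	0.88	FGF20	8	16741462
chr8:89442157	T	C	0.03	1.29	MMP16	8	89442157
rs1491942	G	C	0.14	1.30	LRRK2	12	38907075
rs4889603	G	A	0.43	1.15	STX1B	16	30889726
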