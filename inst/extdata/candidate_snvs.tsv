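no	chrom	pos	ref	gene	codons	sift	mutation_taster	gerp	hc_positive
1	chr6	90418252	C	MDN1	GAC7861CAC	DAMAGING	polymorphism	2.23	FALSE
2	chr14	21860964	C	CHD8	CGT5636CAT	DAMAGING	disease causing	5.34	TRUE
3	chr9	125582872	T	PDCL	GAT398GGT	DAMAGING	disease causing	5.47	FALSE
4	chr17	55183450	G	AKAP1	GTG625ATG	DAMAGING	polymorphism	4.22	TRUE
5	chr15	39885853	G	THBS1	GGA3251GAA	DAMAGING	disease causing	5.78	TRUE
6	chr16	16170185	G	ABCC1	GGG1915TGG	DAMAGING	disease causing	4.11	FALSE
7	chr1	1470881	G	TMEM240	TCG380TTG	DAMAGING	disease causing	3.37	TRUE
8	chr7	73279329	C	WBSCR28	CAG79AAG	DAMAGING	polymorphism	4.43	FALSE
9	chr9	2717768	C	KCNV2	TCC29TGC	DAMAGING	disease causing	4.45	TRUE
10	chr7	99160120	A	ZNF655	-	-	-	3.92	TRUE
11	chr15	41275952	G	INO80	-	-	-	2.69	FALSE
12	chr10	116225553	G	ABLIM1	CGG1345TGG	DAMAGING	disease causing	3.37	FALSE
13	chr1	26368197	T	SLC30A2	ATG685GTG	DAMAGING	disease causing	5.6	FALSE
14	chr20	30232655	T	COX4I2	GTG464GCG	DAMAGING	disease causing	4.38	TRUE
15	chr6	167570520	G	GPR31	ACG800ATG	DAMAGING	polymorphism	2.65	FALSE
16	chr6	168366533	G	MLLT4	GGA4993AGA	DAMAGING	disease causing	5.03	FALSE
17	chr16	20492206	C	ACSM2A	ACG1472ATG	DAMAGING	polymorphism	3.26	FALSE
18	chr20	420894	C	TBC1D20	GTG766ATG	DAMAGING	disease causing	5.65	FALSE
19	chr9	110249480	G	KLF4	-	-	-	3.45	FALSE
20	chr3	196921405	A	DLG1	ATC374ACC	TOLERATED	disease causing	5.17	FALSE
21	chr6	152536152	C	SYNE1	CGT22022CAT	TOLERATED	disease causing	5.07	TRUE
22	chr7	87051466	T	ABCB4	ATT2287GTT	TOLERATED	polymorphism	4.85	FALSE
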