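##fileformat=VCFv4.2
##source=afprs
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S00001	S00002	S00003	S00004	S00005	S00006	S00007	S00008	S00009	S00010	S00011	S00012
7	1000	rs3807989	A	G	.	PASS	.	GT	0/0	0/0	0/1	1/1	0/0	1/1	0/1	0/0	1/1	1/1	1/1	0/1
12	2000	rs11047543	G	A	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1
14	3000	rs28631169	C	T	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0
16	4000	rs2106261	C	T	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/0
1	5000	rs13376333	C	T	.	PASS	.	GT	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0
11	6000	rs75190942	C	A	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0
4	7000	rs2200733	C	T	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0
4	8000	rs6838973	T	C	.	PASS	.	GT	0/1	0/1	1/1	0/0	0/0	0/1	0/1	0/1	0/1	1/1	1/1	0/1
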