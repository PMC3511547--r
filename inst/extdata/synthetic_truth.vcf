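##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA19001	NA19002	NA19003	NA19004
22	16050000	rs001	A	G	.	.	.	GT	0/1	0/0	0/0	0/1
22	16075000	rs002	C	T	.	.	.	GT	0/0	0/0	0/0	0/0
22	16100000	rs003	G	A	.	.	.	GT	0/1	0/1	0/0	0/0
22	16125000	rs004	T	C	.	.	.	GT	1/1	0/1	0/0	0/1
22	16150000	rs005	A	G	.	.	.	GT	0/1	0/0	0/0	0/0
22	16175000	rs006	C	T	.	.	.	GT	1/1	0/1	0/0	0/0
22	16200000	rs007	G	A	.	.	.	GT	0/1	0/1	0/1	0/1
22	16225000	rs008	T	C	.	.	.	GT	0/0	0/1	0/1	0/0
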