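##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12	S13	S14	S15	S16	S17	S18	S19	S20
1	11000	snp0001	A	G	.	PASS	.	GT	0|1	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	0|0	1|0	0|0	1|0	0|1	0|0
1	12000	causal1	A	G	.	PASS	.	GT	0|1	1|0	0|1	1|0	1|0	1|0	0|0	0|0	1|1	0|1	0|0	0|0	1|1	1|0	1|0	1|1	0|0	1|0	1|1	0|1
1	13000	snp0003	A	G	.	PASS	.	GT	0|1	0|0	0|0	1|0	0|0	1|0	0|1	0|1	0|1	0|1	0|0	0|0	1|1	1|0	0|0	1|1	0|0	1|0	1|1	0|0
1	14000	snp0004	A	G	.	PASS	.	GT	0|1	0|0	0|0	1|0	1|0	0|0	0|0	0|1	0|1	0|1	0|0	0|0	1|1	1|0	0|0	0|0	0|0	1|0	0|0	0|0
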