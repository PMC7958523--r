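##fileformat=VCFv4.2
##source=snprisk synthetic fixture (hand-written toy data, not real genotypes)
##contig=<ID=11>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5
11	1219991	varA	G	T	.	PASS	.	GT	0/0	0/1	1/1	0|1	./.
11	2400000	varB	C	A	.	PASS	.	GT	0/1	0/0	0/0	1/1	0/1
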