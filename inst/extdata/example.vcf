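##fileformat=VCFv4.2
##source=introscan-example
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	rec1	line1	don1	out1
chr1	101	.	A	T	.	PASS	.	GT:DP	0/0:31	1/1:28	1/1:30	0/0:33
chr1	220	.	G	C	.	PASS	.	GT:DP	0/0:29	1/1:25	1/1:27	0/0:30
chr1	305	.	C	A	.	PASS	.	GT:DP	0/0:4	1/1:26	1/1:31	0/0:29
chr1	420	.	T	G	.	PASS	.	GT:DP	0/0:30	0/1:24	1/1:28	0/0:27
chr1	512	.	A	AGG	.	PASS	.	GT:DP	0/0:32	0/0:30	1/1:26	0/0:31
chr1	630	.	G	A	.	PASS	.	GT:DP	0/0:28	./.:.	1/1:29	0/0:26
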