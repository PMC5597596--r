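##fileformat=VCFv4.2
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##INFO=<ID=DP4,Number=4,Type=Integer,Description="Strand depths: ref-fwd,ref-rev,alt-fwd,alt-rev">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward-strand allelic depths">
##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse-strand allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	PROBAND
1	10234	.	A	G	61	PASS	MQ=52;DP4=7,6,5,8	GT	0/1
1	20456	.	C	CT	45	PASS	MQ=48	GT:ADF:ADR	0/1:3,4:5,2
2	5120	.	G	T,A	72	PASS	MQ=55	GT:ADF:ADR	1/2:0,6,3:1,4,5
2	9000	.	T	C	33	PASS	MQ=41;DP4=2,3,1,1	GT	1/1
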