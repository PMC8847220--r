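##fileformat=VCFv4.2
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	HG00096	HG00770	HG01992	HG02230	HG02231
chr1	10	rs001	T	C	.	PASS	.	GT	0|0	1|1	0|0	0|0	0|0
chr1	26	rs002	C	T	.	PASS	.	GT	0|0	1|1	0|0	0|0	0|0
chr1	40	sv001	T	<CN0>	.	PASS	SVTYPE=CNV	GT	0|0	1|0	0|0	0|0	0|0
chr1	55	rs003	CAT	C,CATTTT	.	PASS	.	GT	0|0	0|0	2|2	2|2	0|0
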