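##fileformat=VCFv4.2
##source=gbsblup-toy
##contig=<ID=1>
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4
1	10	m01	A	C	.	.	.	AD	10,10	10,10	10,10	10,10
1	20	m02	A	C	.	.	.	AD	150,150	150,150	150,150	150,150
1	30	m03	A	C	.	.	.	AD	2,2	2,2	2,2	2,2
1	40	m04	A	C	.	.	.	AD	0,0	0,0	10,10	10,10
1	50	m05	A	C	.	.	.	AD	0,0	10,10	10,10	10,10
1	60	m06	A	C	.	.	.	AD	20,0	20,0	19,1	19,1
1	70	m07	A	C	.	.	.	AD	0,20	0,20	1,19	1,19
1	80	m08	A	C	.	.	.	AD	12,8	12,8	12,8	12,8
1	90	m09	A	C	.	.	.	AD	5,15	5,15	5,15	5,15
1	100	m10	A	C	.	.	.	AD	8,12	8,12	8,12	8,12
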