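##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=.,Type=String,Description="alt|consequence|gene">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I-1	I-2	II-1	II-2	II-3	II-4	II-5	II-6	II-7	II-8	II-9	II-10	II-11	II-12	III-1	III-2	III-3	III-4	III-5	III-6	III-7	III-8	III-9	III-10	III-11	III-12	III-13	III-14	III-15	III-16
5	6684645	.	T	C	.	PASS	ANN=C|missense|CAUSAL;CADD=36.9	GT	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/1
6	138872061	.	A	T	.	PASS	ANN=T|missense|BG001;CADD=39.2	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
5	114577980	.	T	C	.	PASS	ANN=C|missense|BG002;CADD=12.5	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
17	42718117	.	C	A	.	PASS	ANN=A|other|BG003;CADD=23	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
4	46570390	.	C	T	.	PASS	ANN=T|missense|BG004;CADD=32.3	GT	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
6	73237237	.	A	T	.	PASS	ANN=T|missense|BG005;CADD=39.7	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
21	143316223	.	G	C	.	PASS	ANN=C|nonsense|BG006;CADD=37.1	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0
9	194934776	.	T	C	.	PASS	ANN=C|other|BG007;CADD=25.9	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0
10	5846773	.	G	T	.	PASS	ANN=T|other|BG008;CADD=24	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
8	101013838	.	T	C	.	PASS	ANN=C|nonsense|BG009;CADD=31.2	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
12	69489266	.	G	T	.	PASS	ANN=T|missense|BG010;CADD=22.2	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0
8	109236727	.	C	A	.	PASS	ANN=A|nonsense|BG011;CADD=24.9	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
7	188852469	.	G	T	.	PASS	ANN=T|missense|BG012;CADD=27.6	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0
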