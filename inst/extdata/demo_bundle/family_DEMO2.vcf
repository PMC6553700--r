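##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=.,Type=String,Description="alt|consequence|gene">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I-1	II-1	II-2	II-3	II-4	III-1	III-2	III-3	III-4	III-5	III-6	III-7	III-8	III-9	III-10
15	104015840	.	A	C	.	PASS	ANN=C|missense|CAUSAL;CADD=37.9	GT	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1
8	123405629	.	C	G	.	PASS	ANN=G|missense|BG001;CADD=27.1	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
16	111717848	.	T	G	.	PASS	ANN=G|missense|BG002;CADD=34.1	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
21	174616994	.	G	C	.	PASS	ANN=C|missense|BG003;CADD=16.2	GT	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0
8	82477681	.	T	A	.	PASS	ANN=A|other|BG004;CADD=35.5	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	66008762	.	G	C	.	PASS	ANN=C|other|BG005;CADD=37.5	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
3	3385071	.	A	G	.	PASS	ANN=G|other|BG006;CADD=14.4	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
18	134853660	.	G	T	.	PASS	ANN=T|other|BG007;CADD=27.9	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0
15	182674681	.	C	A	.	PASS	ANN=A|other|BG008;CADD=28.2	GT	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/1
16	4248731	.	C	G	.	PASS	ANN=G|other|BG009;CADD=12	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
6	16464779	.	C	G	.	PASS	ANN=G|missense|BG010;CADD=39.1	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0
19	105097084	.	C	G	.	PASS	ANN=G|missense|BG011;CADD=14.8	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
X	75908541	.	A	C	.	PASS	ANN=C|other|BG012;CADD=21.8	GT	0/1	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/1
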