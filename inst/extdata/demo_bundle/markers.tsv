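family_id	individual_id	marker_id	physical_pos	allele1_bp	allele2_bp
DEMO1	I-1	D5S001	6102904	172	166
DEMO1	I-1	D5S002	6331175	162	160
DEMO1	I-1	D5S003	6353658	244	254
DEMO1	I-1	D5S004	7553514	290	280
DEMO1	I-2	D5S001	6102904	172	162
DEMO1	I-2	D5S002	6331175	162	160
DEMO1	I-2	D5S003	6353658	248	250
DEMO1	I-2	D5S004	7553514	290	280
DEMO1	II-1	D5S001	6102904	166	162
DEMO1	II-1	D5S002	6331175	160	160
DEMO1	II-1	D5S003	6353658	254	250
DEMO1	II-1	D5S004	7553514	280	280
DEMO1	II-2	D5S001	6102904	164	162
DEMO1	II-2	D5S002	6331175	174	166
DEMO1	II-2	D5S003	6353658	250	246
DEMO1	II-2	D5S004	7553514	280	284
DEMO1	II-3	D5S001	6102904	172	172
DEMO1	II-3	D5S002	6331175	162	162
DEMO1	II-3	D5S003	6353658	244	248
DEMO1	II-3	D5S004	7553514	290	290
DEMO1	II-4	D5S001	6102904	174	162
DEMO1	II-4	D5S002	6331175	172	170
DEMO1	II-4	D5S003	6353658	246	248
DEMO1	II-4	D5S004	7553514	284	280
DEMO1	II-5	D5S001	6102904	172	162
DEMO1	II-5	D5S002	6331175	162	160
DEMO1	II-5	D5S003	6353658	244	250
DEMO1	II-5	D5S004	7553514	290	280
DEMO1	II-6	D5S001	6102904	174	166
DEMO1	II-6	D5S002	6331175	166	162
DEMO1	II-6	D5S003	6353658	240	250
DEMO1	II-6	D5S004	7553514	294	284
DEMO1	II-7	D5S001	6102904	172	172
DEMO1	II-7	D5S002	6331175	162	162
DEMO1	II-7	D5S003	6353658	244	248
DEMO1	II-7	D5S004	7553514	290	290
DEMO1	II-8	D5S001	6102904	160	160
DEMO1	II-8	D5S002	6331175	168	174
DEMO1	II-8	D5S003	6353658	250	252
DEMO1	II-8	D5S004	7553514	282	290
DEMO1	II-9	D5S001	6102904	166	162
DEMO1	II-9	D5S002	6331175	160	160
DEMO1	II-9	D5S003	6353658	254	250
DEMO1	II-9	D5S004	7553514	280	280
DEMO1	II-10	D5S001	6102904	168	162
DEMO1	II-10	D5S002	6331175	166	162
DEMO1	II-10	D5S003	6353658	254	240
DEMO1	II-10	D5S004	7553514	280	286
DEMO1	II-11	D5S001	6102904	172	162
DEMO1	II-11	D5S002	6331175	162	160
DEMO1	II-11	D5S003	6353658	244	250
DEMO1	II-11	D5S004	7553514	290	280
DEMO1	II-12	D5S001	6102904	162	172
DEMO1	II-12	D5S002	6331175	172	160
DEMO1	II-12	D5S003	6353658	242	248
DEMO1	II-12	D5S004	7553514	284	284
DEMO1	III-1	D5S001	6102904	162	164
DEMO1	III-1	D5S002	6331175	160	174
DEMO1	III-1	D5S003	6353658	250	250
DEMO1	III-1	D5S004	7553514	280	280
DEMO1	III-2	D5S001	6102904	162	162
DEMO1	III-2	D5S002	6331175	160	166
DEMO1	III-2	D5S003	6353658	250	246
DEMO1	III-2	D5S004	7553514	280	284
DEMO1	III-3	D5S001	6102904	172	174
DEMO1	III-3	D5S002	6331175	162	172
DEMO1	III-3	D5S003	6353658	248	246
DEMO1	III-3	D5S004	7553514	290	284
DEMO1	III-4	D5S001	6102904	172	174
DEMO1	III-4	D5S002	6331175	162	172
DEMO1	III-4	D5S003	6353658	244	246
DEMO1	III-4	D5S004	7553514	290	284
DEMO1	III-5	D5S001	6102904	172	162
DEMO1	III-5	D5S002	6331175	162	170
DEMO1	III-5	D5S003	6353658	244	248
DEMO1	III-5	D5S004	7553514	290	280
DEMO1	III-6	D5S001	6102904	172	162
DEMO1	III-6	D5S002	6331175	162	170
DEMO1	III-6	D5S003	6353658	248	248
DEMO1	III-6	D5S004	7553514	290	280
DEMO1	III-7	D5S001	6102904	174	162
DEMO1	III-7	D5S002	6331175	166	160
DEMO1	III-7	D5S003	6353658	240	250
DEMO1	III-7	D5S004	7553514	294	280
DEMO1	III-8	D5S001	6102904	172	166
DEMO1	III-8	D5S002	6331175	162	162
DEMO1	III-8	D5S003	6353658	244	250
DEMO1	III-8	D5S004	7553514	290	284
DEMO1	III-9	D5S001	6102904	172	166
DEMO1	III-9	D5S002	6331175	162	162
DEMO1	III-9	D5S003	6353658	244	250
DEMO1	III-9	D5S004	7553514	290	284
DEMO1	III-10	D5S001	6102904	172	160
DEMO1	III-10	D5S002	6331175	162	168
DEMO1	III-10	D5S003	6353658	244	250
DEMO1	III-10	D5S004	7553514	290	282
DEMO1	III-11	D5S001	6102904	160	172
DEMO1	III-11	D5S002	6331175	168	162
DEMO1	III-11	D5S003	6353658	250	248
DEMO1	III-11	D5S004	7553514	282	290
DEMO1	III-12	D5S001	6102904	162	162
DEMO1	III-12	D5S002	6331175	160	162
DEMO1	III-12	D5S003	6353658	250	240
DEMO1	III-12	D5S004	7553514	280	286
DEMO1	III-13	D5S001	6102904	162	162
DEMO1	III-13	D5S002	6331175	160	172
DEMO1	III-13	D5S003	6353658	250	242
DEMO1	III-13	D5S004	7553514	280	284
DEMO1	III-14	D5S001	6102904	172	172
DEMO1	III-14	D5S002	6331175	162	160
DEMO1	III-14	D5S003	6353658	244	248
DEMO1	III-14	D5S004	7553514	290	284
DEMO1	III-15	D5S001	6102904	172	172
DEMO1	III-15	D5S002	6331175	162	160
DEMO1	III-15	D5S003	6353658	244	248
DEMO1	III-15	D5S004	7553514	290	284
DEMO1	III-16	D5S001	6102904	172	172
DEMO1	III-16	D5S002	6331175	162	160
DEMO1	III-16	D5S003	6353658	244	248
DEMO1	III-16	D5S004	7553514	290	284
DEMO2	I-1	D15S001	103480353	134	128
DEMO2	I-1	D15S002	103896596	260	268
DEMO2	I-1	D15S003	104353337	222	228
DEMO2	I-1	D15S004	104423215	272	270
DEMO2	II-1	D15S001	103480353	128	126
DEMO2	II-1	D15S002	103896596	268	274
DEMO2	II-1	D15S003	104353337	228	222
DEMO2	II-1	D15S004	104423215	270	262
DEMO2	II-2	D15S001	103480353	120	134
DEMO2	II-2	D15S002	103896596	264	264
DEMO2	II-2	D15S003	104353337	230	226
DEMO2	II-2	D15S004	104423215	264	268
DEMO2	II-3	D15S001	103480353	134	122
DEMO2	II-3	D15S002	103896596	260	262
DEMO2	II-3	D15S003	104353337	222	224
DEMO2	II-3	D15S004	104423215	272	262
DEMO2	II-4	D15S001	103480353	134	132
DEMO2	II-4	D15S002	103896596	272	274
DEMO2	II-4	D15S003	104353337	232	228
DEMO2	II-4	D15S004	104423215	274	266
DEMO2	III-1	D15S001	103480353	134	128
DEMO2	III-1	D15S002	103896596	264	268
DEMO2	III-1	D15S003	104353337	226	228
DEMO2	III-1	D15S004	104423215	268	270
DEMO2	III-2	D15S001	103480353	134	126
DEMO2	III-2	D15S002	103896596	264	274
DEMO2	III-2	D15S003	104353337	226	222
DEMO2	III-2	D15S004	104423215	268	262
DEMO2	III-3	D15S001	103480353	134	128
DEMO2	III-3	D15S002	103896596	264	268
DEMO2	III-3	D15S003	104353337	226	228
DEMO2	III-3	D15S004	104423215	268	270
DEMO2	III-4	D15S001	103480353	134	126
DEMO2	III-4	D15S002	103896596	264	274
DEMO2	III-4	D15S003	104353337	226	222
DEMO2	III-4	D15S004	104423215	268	262
DEMO2	III-5	D15S001	103480353	134	132
DEMO2	III-5	D15S002	103896596	260	274
DEMO2	III-5	D15S003	104353337	222	228
DEMO2	III-5	D15S004	104423215	272	266
DEMO2	III-6	D15S001	103480353	134	134
DEMO2	III-6	D15S002	103896596	260	272
DEMO2	III-6	D15S003	104353337	222	232
DEMO2	III-6	D15S004	104423215	272	274
DEMO2	III-7	D15S001	103480353	122	134
DEMO2	III-7	D15S002	103896596	262	272
DEMO2	III-7	D15S003	104353337	224	232
DEMO2	III-7	D15S004	104423215	262	274
DEMO2	III-8	D15S001	103480353	122	132
DEMO2	III-8	D15S002	103896596	262	274
DEMO2	III-8	D15S003	104353337	224	228
DEMO2	III-8	D15S004	104423215	262	266
DEMO2	III-9	D15S001	103480353	134	134
DEMO2	III-9	D15S002	103896596	260	272
DEMO2	III-9	D15S003	104353337	222	232
DEMO2	III-9	D15S004	104423215	272	274
DEMO2	III-10	D15S001	103480353	134	132
DEMO2	III-10	D15S002	103896596	260	274
DEMO2	III-10	D15S003	104353337	222	228
DEMO2	III-10	D15S004	104423215	272	266
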