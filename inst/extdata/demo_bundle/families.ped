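DEMO1	I-1	0	0	1	2	37	66
DEMO1	I-2	0	0	2	1	0	75
DEMO1	II-1	I-1	I-2	1	1	0	57
DEMO1	II-2	0	0	2	1	0	26
DEMO1	II-3	I-1	I-2	1	2	31	64
DEMO1	II-4	0	0	2	1	0	61
DEMO1	II-5	I-1	I-2	2	2	26	41
DEMO1	II-6	0	0	1	1	0	69
DEMO1	II-7	I-1	I-2	2	2	37	56
DEMO1	II-8	0	0	1	1	0	34
DEMO1	II-9	I-1	I-2	1	1	0	46
DEMO1	II-10	0	0	2	1	0	70
DEMO1	II-11	I-1	I-2	1	2	34	38
DEMO1	II-12	0	0	2	1	0	52
DEMO1	III-1	II-1	II-2	1	1	0	40
DEMO1	III-2	II-1	II-2	1	1	0	45
DEMO1	III-3	II-3	II-4	1	1	0	53
DEMO1	III-4	II-3	II-4	1	2	34	59
DEMO1	III-5	II-3	II-4	2	2	27	61
DEMO1	III-6	II-3	II-4	2	1	0	43
DEMO1	III-7	II-6	II-5	2	1	0	56
DEMO1	III-8	II-6	II-5	2	2	37	49
DEMO1	III-9	II-6	II-5	2	2	41	58
DEMO1	III-10	II-8	II-7	2	2	49	60
DEMO1	III-11	II-8	II-7	2	1	0	64
DEMO1	III-12	II-9	II-10	2	1	0	68
DEMO1	III-13	II-11	II-12	2	1	0	64
DEMO1	III-14	II-11	II-12	1	2	28	31
DEMO1	III-15	II-11	II-12	2	2	37	43
DEMO1	III-16	II-11	II-12	2	2	28	55
DEMO2	I-1	0	0	1	2	39	69
DEMO2	I-2	0	0	2	1	0	52
DEMO2	II-1	I-1	I-2	2	1	0	61
DEMO2	II-2	0	0	1	1	0	71
DEMO2	II-3	I-1	I-2	1	2	37	53
DEMO2	II-4	0	0	2	1	0	41
DEMO2	III-1	II-2	II-1	2	1	0	67
DEMO2	III-2	II-2	II-1	1	1	0	50
DEMO2	III-3	II-2	II-1	2	1	0	63
DEMO2	III-4	II-2	II-1	2	1	0	74
DEMO2	III-5	II-3	II-4	2	2	32	52
DEMO2	III-6	II-3	II-4	1	2	35	69
DEMO2	III-7	II-3	II-4	1	1	0	51
DEMO2	III-8	II-3	II-4	1	1	0	49
DEMO2	III-9	II-3	II-4	1	2	18	56
DEMO2	III-10	II-3	II-4	2	2	26	48
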