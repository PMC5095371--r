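sample	group	cross	snv	indel
144F2-1	I	intraspecific	3	0
144F2-2	I	intraspecific	2	0
144F2-3	I	intraspecific	2	0
144F2-4	I	intraspecific	1	0
144F2-5	I	intraspecific	5	0
144F2-6	I	intraspecific	4	1
144F2-7	I	intraspecific	0	0
144F2-8	I	intraspecific	6	1
144F2-9	I	intraspecific	3	0
144F2-10	I	intraspecific	2	1
144F2-11	I	intraspecific	0	0
144F2-12	I	intraspecific	2	0
144F2-13	I	intraspecific	4	0
144F2-14	I	intraspecific	3	0
144F2-15	I	intraspecific	3	1
144F2-16	I	intraspecific	4	0
144F2-17	I	intraspecific	5	0
144F2-18	I	intraspecific	4	2
144F2-19	I	intraspecific	4	2
144F2-20	I	intraspecific	2	1
144F2-21	I	intraspecific	5	0
144F2-22	I	intraspecific	1	0
144F2-23	I	intraspecific	3	1
144F2-24	I	intraspecific	3	1
GZTH-5	II	intraspecific	4	4
GZTH-S1	II	intraspecific	2	1
GZTH-S2	II	intraspecific	1	0
GZTH-S3	II	intraspecific	4	0
GZTH-S4	II	intraspecific	5	0
GZTH-S5	II	intraspecific	4	1
GZTH-S7	II	intraspecific	1	0
GZTH-S8	II	intraspecific	2	1
GZTH-S9	II	intraspecific	2	0
NE1	III	interspecific	5	0
NE2	III	interspecific	8	2
NE3	III	interspecific	3	1
NE4	III	interspecific	12	1
NE5	III	interspecific	4	1
NE6	III	interspecific	3	2
NE7	III	interspecific	4	1
NE8	III	interspecific	4	0
NE9	III	interspecific	6	1
NE10	III	interspecific	6	2
NE11	III	interspecific	4	1
NE12	III	interspecific	7	2
NE13	III	interspecific	5	1
NE14	III	interspecific	0	0
NE15	III	interspecific	4	1
NE16	III	interspecific	2	1
NE17	III	interspecific	3	1
NE18	III	interspecific	4	0
NE19	III	interspecific	7	2
NE20	III	interspecific	7	1
NE21	III	interspecific	11	2
NE22	III	interspecific	3	0
NE23	III	interspecific	5	0
NE24	III	interspecific	3	0
NE25	III	interspecific	4	0
NE26	III	interspecific	6	0
NE27	III	interspecific	3	2
NE28	III	interspecific	4	2
NE29	III	interspecific	4	0
NE30	III	interspecific	3	1
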