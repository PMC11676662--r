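locus	allele	frequency	frequency_unit	n	n_unit
A	A*01	12	percent	11516	alleles
A	A*02	26	percent	11516	alleles
A	A*03	9	percent	11516	alleles
A	A*11	8	percent	11516	alleles
A	A*23	3	percent	11516	alleles
A	A*24	12	percent	11516	alleles
A	A*25	3	percent	11516	alleles
A	A*26	5	percent	11516	alleles
A	A*29	2	percent	11516	alleles
A	A*30	2	percent	11516	alleles
A	A*31	2	percent	11516	alleles
A	A*32	4	percent	11516	alleles
A	A*33	3	percent	11516	alleles
A	A*36	4	percent	11516	alleles
A	A*68	3	percent	11516	alleles
B	B*07	5	percent	12020	alleles
B	B*08	6	percent	12020	alleles
B	B*13	3	percent	12020	alleles
B	B*14	2	percent	12020	alleles
B	B*15	3	percent	12020	alleles
B	B*18	10	percent	12020	alleles
B	B*27	4	percent	12020	alleles
B	B*35	14	percent	12020	alleles
B	B*38	3	percent	12020	alleles
B	B*39	3	percent	12020	alleles
B	B*40	5	percent	12020	alleles
B	B*41	2	percent	12020	alleles
B	B*44	8	percent	12020	alleles
B	B*47	0	percent	12020	alleles
B	B*49	2	percent	12020	alleles
B	B*50	2	percent	12020	alleles
B	B*51	9	percent	12020	alleles
B	B*52	4	percent	12020	alleles
B	B*53	2	percent	12020	alleles
B	B*55	2	percent	12020	alleles
B	B*56	1	percent	12020	alleles
B	B*57	1	percent	12020	alleles
B	B*58	2	percent	12020	alleles
B	B*73	0	percent	12020	alleles
B	B*78	3	percent	12020	alleles
C	C*01	5	percent	3224	alleles
C	C*02	7	percent	3224	alleles
C	C*03	7	percent	3224	alleles
C	C*04	15	percent	3224	alleles
C	C*05	3	percent	3224	alleles
C	C*06	9	percent	3224	alleles
C	C*07	26	percent	3224	alleles
C	C*08	3	percent	3224	alleles
C	C*12	13	percent	3224	alleles
C	C*14	3	percent	3224	alleles
C	C*15	5	percent	3224	alleles
C	C*16	3	percent	3224	alleles
C	C*17	1	percent	3224	alleles
DRB1	DRB1*01	8	percent	13872	alleles
DRB1	DRB1*03	11	percent	13872	alleles
DRB1	DRB1*04	9	percent	13872	alleles
DRB1	DRB1*07	7	percent	13872	alleles
DRB1	DRB1*08	2	percent	13872	alleles
DRB1	DRB1*10	1	percent	13872	alleles
DRB1	DRB1*11	19	percent	13872	alleles
DRB1	DRB1*12	2	percent	13872	alleles
DRB1	DRB1*13	15	percent	13872	alleles
DRB1	DRB1*14	7	percent	13872	alleles
DRB1	DRB1*15	9	percent	13872	alleles
DRB1	DRB1*16	10	percent	13872	alleles
DQB1	DQB1*02	21	percent	6656	alleles
DQB1	DQB1*03	29	percent	6656	alleles
DQB1	DQB1*04	2	percent	6656	alleles
DQB1	DQB1*05	30	percent	6656	alleles
DQB1	DQB1*06	18	percent	6656	alleles
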