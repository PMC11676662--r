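locus	allele1	allele2	frequency_pct	n_subjects
A	A*01	A*01	2.41	373
A	A*01	A*02	10.46	373
A	A*01	A*03	1.61	373
A	A*01	A*24	4.29	373
A	A*01	A*32	0.8	373
A	A*02	A*02	6.97	373
A	A*02	A*03	6.43	373
A	A*02	A*11	4.02	373
A	A*02	A*24	6.17	373
A	A*02	A*25	1.34	373
A	A*02	A*26	2.95	373
A	A*02	A*29	0	373
A	A*02	A*30	1.07	373
A	A*02	A*32	2.14	373
A	A*03	A*32	0.54	373
A	A*03	A*33	0	373
A	A*11	A*24	0.8	373
A	A*23	A*68	0	373
A	A*24	A*24	1.88	373
A	A*24	A*25	1.61	373
A	A*25	A*33	0	373
A	A*26	A*26	0	373
A	A*31	A*32	0.8	373
B	B*07	B*35	1.62	371
B	B*07	B*44	1.35	371
B	B*08	B*15	0.27	371
B	B*08	B*18	2.7	371
B	B*08	B*35	1.89	371
B	B*08	B*38	0.27	371
B	B*08	B*39	0.81	371
B	B*08	B*40	1.08	371
B	B*08	B*44	1.08	371
B	B*08	B*51	1.35	371
B	B*08	B*55	0	371
B	B*08	B*73	0	371
B	B*13	B*27	0	371
B	B*13	B*35	0.81	371
B	B*13	B*51	1.35	371
B	B*15	B*18	1.89	371
B	B*15	B*35	2.7	371
B	B*18	B*38	1.08	371
B	B*18	B*39	0.27	371
B	B*18	B*40	1.35	371
B	B*18	B*44	2.16	371
B	B*18	B*51	2.7	371
B	B*27	B*35	0.81	371
B	B*27	B*51	0.54	371
B	B*27	B*57	0.27	371
B	B*35	B*40	1.62	371
B	B*35	B*44	2.16	371
B	B*35	B*51	2.16	371
B	B*35	B*52	1.35	371
B	B*38	B*57	0.27	371
B	B*40	B*47	0	371
B	B*40	B*51	0.81	371
B	B*44	B*51	1.35	371
B	B*51	B*58	0.27	371
DRB1	DRB1*01	DRB1*03	3.73	134
DRB1	DRB1*01	DRB1*07	0.75	134
DRB1	DRB1*01	DRB1*11	2.24	134
DRB1	DRB1*01	DRB1*14	0.75	134
DRB1	DRB1*01	DRB1*15	0.75	134
DRB1	DRB1*01	DRB1*16	0.75	134
DRB1	DRB1*03	DRB1*11	2.99	134
DRB1	DRB1*03	DRB1*14	2.24	134
DRB1	DRB1*03	DRB1*15	2.99	134
DRB1	DRB1*03	DRB1*16	2.24	134
DRB1	DRB1*04	DRB1*13	2.99	134
DRB1	DRB1*04	DRB1*15	1.49	134
DRB1	DRB1*04	DRB1*16	1.49	134
DRB1	DRB1*07	DRB1*11	5.22	134
DRB1	DRB1*07	DRB1*14	0.75	134
DRB1	DRB1*07	DRB1*15	0.75	134
DRB1	DRB1*10	DRB1*14	0	134
DRB1	DRB1*11	DRB1*11	2.99	134
DRB1	DRB1*11	DRB1*12	0.75	134
DRB1	DRB1*11	DRB1*15	4.48	134
DRB1	DRB1*11	DRB1*16	5.22	134
DRB1	DRB1*14	DRB1*15	0	134
DRB1	DRB1*14	DRB1*16	2.99	134
DRB1	DRB1*15	DRB1*16	2.24	134
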