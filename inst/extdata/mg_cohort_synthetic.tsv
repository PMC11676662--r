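subject_id	A_1	A_2	B_1	B_2	C_1	C_2	DRB1_1	DRB1_2	DQB1_1	DQB1_2	sex	age_at_onset	onset_class	mgfa_max	serotype	thymic_status	autoimmune	titin_ryr
MG01	A*01	A*01	B*08	B*40	C*01	C*15	DRB1*01	DRB1*03	DQB1*02	DQB1*03	F	20	EOMG	IIA	RAchPos	thymoma	TRUE	none
MG02	A*01	A*02	B*18	B*40	C*01	C*15	DRB1*01	DRB1*07	DQB1*02	DQB1*03	F	24	EOMG	IIA	RAchPos	thymoma	TRUE	none
MG03	A*01	A*02	B*18	B*40	C*01	C*15	DRB1*01	DRB1*07	DQB1*02	DQB1*03	F	28	EOMG	IIA	RAchPos	thymoma	TRUE	none
MG04	A*01	A*02	B*35	B*40	C*01	C*16	DRB1*01	DRB1*11	DQB1*02	DQB1*03	F	32	EOMG	IIB	RAchPos	follicular_hyperplasia	TRUE	none
MG05	A*01	A*02	B*35	B*40	C*02	C*03	DRB1*01	DRB1*11	DQB1*02	DQB1*03	F	36	EOMG	IIB	RAchPos	normal_ct	FALSE	none
MG06	A*01	A*03	B*40	B*47	C*02	C*03	DRB1*01	DRB1*14	DQB1*02	DQB1*03	F	45	EOMG	IIB	RAchPos	normal_ct	FALSE	none
MG07	A*01	A*03	B*40	B*47	C*02	C*03	DRB1*01	DRB1*14	DQB1*02	DQB1*05	F	60	LOMG	V	RAchPos	normal_ct	FALSE	none
MG08	A*01	A*03	B*40	B*51	C*02	C*03	DRB1*01	DRB1*15	DQB1*02	DQB1*05	F	10	MGj	V	RAchPos	normal_ct	TRUE	none
MG09	A*01	A*24	B*07	B*35	C*02	C*07	DRB1*01	DRB1*16	DQB1*02	DQB1*05	F	8	MGj	I	dSNMG	normal_ct	TRUE	none
MG10	A*01	A*24	B*07	B*35	C*02	C*07	DRB1*03	DRB1*11	DQB1*02	DQB1*05	F	15	MGj	I	RAchPos	normal_ct	TRUE	none
MG11	A*01	A*32	B*07	B*44	C*02	C*07	DRB1*03	DRB1*14	DQB1*02	DQB1*05	F	19	EOMG	I	RAchPos	normal_ct	TRUE	none
MG12	A*01	A*32	B*08	B*15	C*02	C*07	DRB1*03	DRB1*14	DQB1*03	DQB1*05	F	21	EOMG	I	RAchPos	normal_ct	TRUE	none
MG13	A*02	A*02	B*08	B*18	C*03	C*07	DRB1*03	DRB1*16	DQB1*03	DQB1*05	F	23	EOMG	I	RAchPos	normal_ct	TRUE	none
MG14	A*02	A*02	B*08	B*18	C*03	C*07	DRB1*03	DRB1*16	DQB1*03	DQB1*05	F	25	EOMG	IIA	RAchPos	normal_ct	TRUE	none
MG15	A*02	A*02	B*08	B*35	C*04	C*05	DRB1*03	DRB1*16	DQB1*03	DQB1*05	F	27	EOMG	IIA	RAchPos	normal_ct	FALSE	titin_only
MG16	A*02	A*02	B*08	B*38	C*04	C*06	DRB1*03	DRB1*16	DQB1*03	DQB1*05	F	29	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG17	A*02	A*02	B*08	B*39	C*04	C*06	DRB1*04	DRB1*13	DQB1*03	DQB1*05	F	31	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG18	A*02	A*03	B*08	B*44	C*04	C*06	DRB1*04	DRB1*15	DQB1*03	DQB1*05	F	33	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG19	A*02	A*11	B*08	B*44	C*04	C*07	DRB1*04	DRB1*15	DQB1*03	DQB1*05	F	35	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG20	A*02	A*24	B*08	B*51	C*04	C*07	DRB1*04	DRB1*15	DQB1*03	DQB1*05	F	37	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG21	A*02	A*24	B*08	B*55	C*04	C*07	DRB1*04	DRB1*16	DQB1*03	DQB1*05	F	39	EOMG	IIA	RAchPos	thymoma	FALSE	none
MG22	A*02	A*24	B*08	B*73	C*04	C*07	DRB1*04	DRB1*16	DQB1*03	DQB1*05	F	41	EOMG	IIA	RAchPos	follicular_hyperplasia	FALSE	none
MG23	A*02	A*24	B*13	B*27	C*06	C*07	DRB1*04	DRB1*16	DQB1*03	DQB1*05	F	43	EOMG	IIA	RAchPos	follicular_hyperplasia	FALSE	none
MG24	A*02	A*24	B*13	B*35	C*06	C*07	DRB1*07	DRB1*11	DQB1*03	DQB1*05	F	45	EOMG	IIA	RAchPos	follicular_hyperplasia	FALSE	none
MG25	A*02	A*24	B*13	B*51	C*06	C*07	DRB1*07	DRB1*11	DQB1*03	DQB1*05	F	47	EOMG	IIB	RAchPos	follicular_hyperplasia	FALSE	none
MG26	A*02	A*25	B*15	B*18	C*06	C*07	DRB1*07	DRB1*14	DQB1*03	DQB1*05	F	48	EOMG	IIB	RAchPos	follicular_hyperplasia	FALSE	none
MG27	A*02	A*26	B*18	B*38	C*06	C*07	DRB1*07	DRB1*15	DQB1*03	DQB1*05	F	49	EOMG	IIB	RAchPos	follicular_hyperplasia	FALSE	none
MG28	A*02	A*26	B*18	B*39	C*06	C*07	DRB1*10	DRB1*14	DQB1*03	DQB1*05	F	50	LOMG	IIB	RAchPos	follicular_hyperplasia	FALSE	none
MG29	A*02	A*29	B*18	B*44	C*07	C*12	DRB1*10	DRB1*15	DQB1*05	DQB1*06	F	52	LOMG	IIB	RAchPos	follicular_hyperplasia	FALSE	none
MG30	A*02	A*30	B*18	B*51	C*07	C*12	DRB1*11	DRB1*11	DQB1*05	DQB1*06	F	54	LOMG	IIB	RAchPos	normal_ct	FALSE	titin_and_ryr
MG31	A*02	A*32	B*27	B*35	C*07	C*12	DRB1*11	DRB1*12	DQB1*05	DQB1*06	F	56	LOMG	IIB	RAchPos	normal_ct	FALSE	titin_and_ryr
MG32	A*03	A*32	B*27	B*51	C*07	C*12	DRB1*11	DRB1*15	DQB1*05	DQB1*06	F	58	LOMG	IIB	MuSKPos	normal_ct	FALSE	none
MG33	A*03	A*33	B*27	B*57	C*07	C*12	DRB1*11	DRB1*15	DQB1*05	DQB1*06	M	60	LOMG	IIIB	dSNMG	normal_ct	FALSE	none
MG34	A*11	A*24	B*35	B*44	C*07	C*12	DRB1*11	DRB1*16	DQB1*05	DQB1*06	M	62	LOMG	IIIB	dSNMG	normal_ct	FALSE	none
MG35	A*23	A*68	B*35	B*44	C*07	C*12	DRB1*11	DRB1*16	DQB1*05	DQB1*06	M	64	LOMG	V	dSNMG	normal_ct	FALSE	none
MG36	A*24	A*24	B*35	B*51	C*07	C*12	DRB1*11	DRB1*16	DQB1*05	DQB1*06	M	66	LOMG	V	dSNMG	normal_ct	FALSE	none
MG37	A*24	A*25	B*35	B*52	C*07	C*12	DRB1*11	DRB1*16	DQB1*05	DQB1*06	M	68	LOMG	V	dSNMG	normal_ct	FALSE	none
MG38	A*25	A*33	B*38	B*57	C*12	C*14	DRB1*14	DRB1*15	DQB1*05	DQB1*06	M	70	LOMG	V	dSNMG	normal_ct	FALSE	none
MG39	A*26	A*26	B*44	B*51	C*14	C*15	DRB1*14	DRB1*16	DQB1*05	DQB1*06	M	72	LOMG	V	dSNMG	normal_ct	FALSE	none
MG40	A*31	A*32	B*51	B*58	C*15	C*16	DRB1*15	DRB1*16			M	74	LOMG	V	dSNMG	normal_ct	FALSE	none
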