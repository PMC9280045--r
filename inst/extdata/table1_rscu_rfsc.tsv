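species	amino_acid	codon	rscu	rfsc	anomalous
HbWOX	A	GCU	1.27	31.66	FALSE
JcWOX	A	GCU	0.90	22.52	FALSE
MeWOX	A	GCU	1.37	34.26	FALSE
RcWOX	A	GCU	1.33	33.33	FALSE
HbWOX	A	GCC	0.76	18.92	FALSE
JcWOX	A	GCC	0.54	13.51	FALSE
MeWOX	A	GCC	0.51	12.75	FALSE
RcWOX	A	GCC	0.43	10.64	FALSE
HbWOX	A	GCA	1.84	45.95	FALSE
JcWOX	A	GCA	2.09	52.26	FALSE
MeWOX	A	GCA	1.83	45.82	FALSE
RcWOX	A	GCA	1.90	47.52	FALSE
HbWOX	A	GCG	0.14	3.47	FALSE
JcWOX	A	GCG	0.47	11.71	FALSE
MeWOX	A	GCG	0.29	7.17	FALSE
RcWOX	A	GCG	0.34	8.51	FALSE
HbWOX	C	UGU	1.03	51.55	FALSE
JcWOX	C	UGU	1.13	56.60	FALSE
MeWOX	C	UGU	0.86	43.09	FALSE
RcWOX	C	UGU	0.88	43.94	FALSE
HbWOX	C	UGC	0.97	48.45	FALSE
JcWOX	C	UGC	0.87	43.40	FALSE
MeWOX	C	UGC	1.14	56.91	FALSE
RcWOX	C	UGC	1.12	56.06	FALSE
HbWOX	D	GAU	1.45	72.49	FALSE
JcWOX	D	GAU	1.28	63.86	FALSE
MeWOX	D	GAU	1.37	63.33	TRUE
RcWOX	D	GAU	1.45	72.45	FALSE
HbWOX	D	GAC	0.55	27.51	FALSE
JcWOX	D	GAC	0.72	36.14	FALSE
MeWOX	D	GAC	0.51	36.67	TRUE
RcWOX	D	GAC	0.55	27.55	FALSE
HbWOX	E	GAA	1.20	59.89	FALSE
JcWOX	E	GAA	1.35	67.35	FALSE
MeWOX	E	GAA	1.83	62.87	TRUE
RcWOX	E	GAA	1.27	63.64	FALSE
HbWOX	E	GAG	0.80	40.11	FALSE
JcWOX	E	GAG	0.65	32.65	FALSE
MeWOX	E	GAG	0.29	37.13	TRUE
RcWOX	E	GAG	0.73	36.36	FALSE
HbWOX	F	UUU	1.00	50.22	FALSE
JcWOX	F	UUU	0.98	49.17	FALSE
MeWOX	F	UUU	1.05	52.27	FALSE
RcWOX	F	UUU	1.02	51.16	FALSE
HbWOX	F	UUC	1.00	49.78	FALSE
JcWOX	F	UUC	1.02	50.83	FALSE
MeWOX	F	UUC	0.95	47.73	FALSE
RcWOX	F	UUC	0.98	48.84	FALSE
HbWOX	G	GGU	1.17	29.28	FALSE
JcWOX	G	GGU	1.35	33.87	FALSE
MeWOX	G	GGU	1.06	26.53	FALSE
RcWOX	G	GGU	1.16	29.03	FALSE
HbWOX	G	GGC	0.78	19.42	FALSE
JcWOX	G	GGC	0.52	12.90	FALSE
MeWOX	G	GGC	0.72	17.96	FALSE
RcWOX	G	GGC	0.77	19.35	FALSE
HbWOX	G	GGA	1.37	34.20	FALSE
JcWOX	G	GGA	1.52	37.91	FALSE
MeWOX	G	GGA	1.36	33.88	FALSE
RcWOX	G	GGA	1.34	33.56	FALSE
HbWOX	G	GGG	0.68	17.10	FALSE
JcWOX	G	GGG	0.61	15.32	FALSE
MeWOX	G	GGG	0.87	21.63	FALSE
RcWOX	G	GGG	0.72	18.06	FALSE
HbWOX	H	CAU	0.95	47.37	FALSE
JcWOX	H	CAU	1.02	50.79	FALSE
MeWOX	H	CAU	1.05	64.43	TRUE
RcWOX	H	CAU	1.27	63.53	FALSE
HbWOX	H	CAC	1.05	52.63	FALSE
JcWOX	H	CAC	0.98	49.21	FALSE
MeWOX	H	CAC	0.90	35.57	TRUE
RcWOX	H	CAC	0.73	36.47	FALSE
HbWOX	I	AUU	1.11	37.15	FALSE
JcWOX	I	AUU	1.10	36.62	FALSE
MeWOX	I	AUU	1.09	36.44	FALSE
RcWOX	I	AUU	1.11	37.02	FALSE
HbWOX	I	AUC	1.08	35.97	FALSE
JcWOX	I	AUC	0.93	30.99	FALSE
MeWOX	I	AUC	1.09	36.44	FALSE
RcWOX	I	AUC	1.07	35.71	FALSE
HbWOX	I	AUA	0.81	26.88	FALSE
JcWOX	I	AUA	0.97	32.39	FALSE
MeWOX	I	AUA	0.81	27.12	FALSE
RcWOX	I	AUA	0.82	27.27	FALSE
HbWOX	K	AAA	0.84	41.83	FALSE
JcWOX	K	AAA	0.96	47.95	FALSE
MeWOX	K	AAA	1.57	46.34	TRUE
RcWOX	K	AAA	0.94	47.19	FALSE
HbWOX	K	AAG	1.16	58.17	FALSE
JcWOX	K	AAG	1.04	52.05	FALSE
MeWOX	K	AAG	0.43	53.66	TRUE
RcWOX	K	AAG	1.06	52.81	FALSE
HbWOX	L	UUA	0.73	12.14	FALSE
JcWOX	L	UUA	0.92	15.35	FALSE
MeWOX	L	UUA	0.58	9.64	FALSE
RcWOX	L	UUA	0.74	12.26	FALSE
HbWOX	L	UUG	0.87	14.47	FALSE
JcWOX	L	UUG	0.85	14.17	FALSE
MeWOX	L	UUG	0.92	15.30	FALSE
RcWOX	L	UUG	1.06	17.62	FALSE
HbWOX	L	CUU	1.69	28.18	FALSE
JcWOX	L	CUU	1.84	30.72	FALSE
MeWOX	L	CUU	1.47	24.53	FALSE
RcWOX	L	CUU	1.52	25.29	FALSE
HbWOX	L	CUC	1.02	17.05	FALSE
JcWOX	L	CUC	0.83	13.78	FALSE
MeWOX	L	CUC	1.17	19.50	FALSE
RcWOX	L	CUC	0.78	13.03	FALSE
HbWOX	L	CUA	0.73	12.14	FALSE
JcWOX	L	CUA	0.59	9.84	FALSE
MeWOX	L	CUA	0.72	11.95	FALSE
RcWOX	L	CUA	0.90	14.94	FALSE
HbWOX	L	CUG	0.96	16.02	FALSE
JcWOX	L	CUG	0.97	16.14	FALSE
MeWOX	L	CUG	1.14	19.08	FALSE
RcWOX	L	CUG	1.01	16.86	FALSE
HbWOX	M	AUG	1.00	100.00	FALSE
JcWOX	M	AUG	1.00	100.00	FALSE
MeWOX	M	AUG	1.00	100.00	FALSE
RcWOX	M	AUG	1.00	100.00	FALSE
HbWOX	N	AAU	1.19	59.32	FALSE
JcWOX	N	AAU	1.16	58.00	FALSE
MeWOX	N	AAU	1.18	50.19	TRUE
RcWOX	N	AAU	0.95	47.59	FALSE
HbWOX	N	AAC	0.81	40.68	FALSE
JcWOX	N	AAC	0.84	42.00	FALSE
MeWOX	N	AAC	0.82	49.81	TRUE
RcWOX	N	AAC	1.05	52.41	FALSE
HbWOX	P	CCU	1.39	34.80	FALSE
JcWOX	P	CCU	1.12	27.91	FALSE
MeWOX	P	CCU	1.05	26.25	FALSE
RcWOX	P	CCU	1.33	33.33	FALSE
HbWOX	P	CCC	0.53	13.17	FALSE
JcWOX	P	CCC	0.68	17.05	FALSE
MeWOX	P	CCC	0.90	22.50	FALSE
RcWOX	P	CCC	0.68	17.01	FALSE
HbWOX	P	CCA	1.81	45.13	FALSE
JcWOX	P	CCA	1.71	42.64	FALSE
MeWOX	P	CCA	1.75	43.75	FALSE
RcWOX	P	CCA	1.74	43.54	FALSE
HbWOX	P	CCG	0.28	6.90	FALSE
JcWOX	P	CCG	0.50	12.40	FALSE
MeWOX	P	CCG	0.30	7.50	FALSE
RcWOX	P	CCG	0.24	6.12	FALSE
HbWOX	Q	CAA	1.21	60.68	FALSE
JcWOX	Q	CAA	1.25	62.58	FALSE
MeWOX	Q	CAA	1.75	58.77	TRUE
RcWOX	Q	CAA	1.24	61.88	FALSE
HbWOX	Q	CAG	0.79	39.32	FALSE
JcWOX	Q	CAG	0.75	37.42	FALSE
MeWOX	Q	CAG	0.30	41.23	TRUE
RcWOX	Q	CAG	0.76	38.12	FALSE
HbWOX	R	CGU	0.61	10.14	FALSE
JcWOX	R	CGU	0.53	8.82	FALSE
MeWOX	R	CGU	0.59	9.82	FALSE
RcWOX	R	CGU	0.42	7.06	FALSE
HbWOX	R	CGC	0.37	6.20	FALSE
JcWOX	R	CGC	0.18	2.94	FALSE
MeWOX	R	CGC	0.18	2.98	FALSE
RcWOX	R	CGC	0.32	5.29	FALSE
HbWOX	R	CGA	0.49	8.17	FALSE
JcWOX	R	CGA	0.42	7.06	FALSE
MeWOX	R	CGA	0.68	11.31	FALSE
RcWOX	R	CGA	0.32	5.29	FALSE
HbWOX	R	CGG	0.25	4.23	FALSE
JcWOX	R	CGG	0.46	7.65	FALSE
MeWOX	R	CGG	0.27	4.46	FALSE
RcWOX	R	CGG	0.25	4.12	FALSE
HbWOX	R	AGA	2.74	45.63	FALSE
JcWOX	R	AGA	3.25	54.12	FALSE
MeWOX	R	AGA	2.68	44.64	FALSE
RcWOX	R	AGA	3.28	54.71	FALSE
HbWOX	R	AGG	1.54	25.63	FALSE
JcWOX	R	AGG	1.16	19.41	FALSE
MeWOX	R	AGG	1.61	26.79	FALSE
RcWOX	R	AGG	1.41	23.53	FALSE
HbWOX	S	UCU	1.44	23.94	FALSE
JcWOX	S	UCU	1.40	23.31	FALSE
MeWOX	S	UCU	1.29	21.49	FALSE
RcWOX	S	UCU	1.31	21.77	FALSE
HbWOX	S	UCC	0.72	11.97	FALSE
JcWOX	S	UCC	0.94	15.68	FALSE
MeWOX	S	UCC	0.88	14.68	FALSE
RcWOX	S	UCC	0.83	13.88	FALSE
HbWOX	S	UCA	1.43	23.77	FALSE
JcWOX	S	UCA	1.37	22.88	FALSE
MeWOX	S	UCA	1.54	25.74	FALSE
RcWOX	S	UCA	1.61	26.81	FALSE
HbWOX	S	UCG	0.25	4.23	FALSE
JcWOX	S	UCG	0.25	4.24	FALSE
MeWOX	S	UCG	0.27	4.47	FALSE
RcWOX	S	UCG	0.25	4.10	FALSE
HbWOX	S	AGU	0.98	16.37	FALSE
JcWOX	S	AGU	0.71	11.86	FALSE
MeWOX	S	AGU	0.88	14.68	FALSE
RcWOX	S	AGU	0.93	15.46	FALSE
HbWOX	S	AGC	1.18	19.72	FALSE
JcWOX	S	AGC	1.32	22.03	FALSE
MeWOX	S	AGC	1.14	18.94	FALSE
RcWOX	S	AGC	1.08	17.98	FALSE
HbWOX	T	ACU	1.50	37.50	FALSE
JcWOX	T	ACU	1.51	37.80	FALSE
MeWOX	T	ACU	1.18	29.57	FALSE
RcWOX	T	ACU	1.62	40.47	FALSE
HbWOX	T	ACC	0.80	20.12	FALSE
JcWOX	T	ACC	0.78	19.51	FALSE
MeWOX	T	ACC	0.82	20.60	FALSE
RcWOX	T	ACC	0.71	17.67	FALSE
HbWOX	T	ACA	1.35	33.84	FALSE
JcWOX	T	ACA	1.39	34.76	FALSE
MeWOX	T	ACA	1.57	39.20	FALSE
RcWOX	T	ACA	1.47	36.74	FALSE
HbWOX	T	ACG	0.34	8.54	FALSE
JcWOX	T	ACG	0.32	7.93	FALSE
MeWOX	T	ACG	0.43	10.63	FALSE
RcWOX	T	ACG	0.20	5.12	FALSE
HbWOX	V	GUU	1.47	36.81	FALSE
JcWOX	V	GUU	1.46	36.43	FALSE
MeWOX	V	GUU	1.37	34.34	FALSE
RcWOX	V	GUU	1.24	31.01	FALSE
HbWOX	V	GUC	0.60	15.00	FALSE
JcWOX	V	GUC	0.85	21.19	FALSE
MeWOX	V	GUC	0.57	14.35	FALSE
RcWOX	V	GUC	0.68	17.05	FALSE
HbWOX	V	GUA	0.75	18.64	FALSE
JcWOX	V	GUA	0.58	14.41	FALSE
MeWOX	V	GUA	0.71	17.83	FALSE
RcWOX	V	GUA	1.15	28.68	FALSE
HbWOX	V	GUG	1.18	29.55	FALSE
JcWOX	V	GUG	1.12	27.97	FALSE
MeWOX	V	GUG	1.34	33.48	FALSE
RcWOX	V	GUG	0.93	23.26	FALSE
HbWOX	W	UGG	1.00	100.00	FALSE
JcWOX	W	UGG	1.00	100.00	FALSE
MeWOX	W	UGG	1.00	100.00	FALSE
RcWOX	W	UGG	1.00	100.00	FALSE
HbWOX	Y	UAU	1.07	53.38	FALSE
JcWOX	Y	UAU	0.98	49.18	FALSE
MeWOX	Y	UAU	1.29	49.14	TRUE
RcWOX	Y	UAU	1.10	55.07	FALSE
HbWOX	Y	UAC	0.93	46.62	FALSE
JcWOX	Y	UAC	1.02	50.82	FALSE
MeWOX	Y	UAC	0.88	50.86	TRUE
RcWOX	Y	UAC	0.90	44.93	FALSE
HbWOX	TER	UGA	1.95	65.00	FALSE
JcWOX	TER	UGA	1.38	2.54	TRUE
MeWOX	TER	UGA	1.55	51.79	FALSE
RcWOX	TER	UGA	1.58	52.81	FALSE
HbWOX	TER	UAA	0.79	26.25	FALSE
JcWOX	TER	UAA	0.95	57.00	TRUE
MeWOX	TER	UAA	1.54	29.50	TRUE
RcWOX	TER	UAA	0.91	30.34	FALSE
HbWOX	TER	UAG	0.26	8.75	FALSE
JcWOX	TER	UAG	0.67	40.46	TRUE
MeWOX	TER	UAG	0.27	18.71	TRUE
RcWOX	TER	UAG	0.51	16.85	FALSE
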