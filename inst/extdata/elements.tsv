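symbol	z	covalent_radius	mass	valence_electrons	block	red	green	blue
H	1	0.31	1.008	1	s	255	255	255
He	2	0.28	4.003	2	s	217	255	255
Li	3	1.28	6.941	1	s	204	128	255
Be	4	0.96	9.012	2	s	194	255	0
B	5	0.84	10.812	3	p	255	181	181
C	6	0.76	12.011	4	p	144	144	144
N	7	0.71	14.007	5	p	48	80	248
O	8	0.66	15.999	6	p	255	13	13
F	9	0.57	18.998	7	p	144	224	80
Ne	10	0.58	20.18	8	p	179	227	245
Na	11	1.66	22.99	1	s	171	92	242
Mg	12	1.41	24.305	2	s	138	255	0
Al	13	1.21	26.982	3	p	191	166	166
Si	14	1.11	28.086	4	p	240	200	160
P	15	1.07	30.974	5	p	255	128	0
S	16	1.05	32.067	6	p	255	255	48
Cl	17	1.02	35.453	7	p	31	240	31
Ar	18	1.06	39.948	8	p	128	209	227
K	19	2.03	39.098	1	s	143	64	212
Ca	20	1.76	40.078	2	s	61	255	0
Sc	21	1.7	44.956	NA	d	230	230	230
Ti	22	1.6	47.867	NA	d	191	194	199
V	23	1.52	50.944	NA	d	166	166	171
Cr	24	1.39	51.996	NA	d	138	153	199
Mn	25	1.39	54.938	NA	d	156	122	199
Fe	26	1.32	55.845	NA	d	224	102	51
Co	27	1.26	58.933	NA	d	240	144	160
Ni	28	1.24	58.693	NA	d	80	208	80
Cu	29	1.32	63.546	NA	d	200	128	51
Zn	30	1.22	65.39	NA	d	125	128	176
Ga	31	1.22	69.723	3	p	194	143	143
Ge	32	1.2	72.61	4	p	102	143	143
As	33	1.19	74.922	5	p	189	128	227
Se	34	1.2	78.96	6	p	255	161	0
Br	35	1.2	79.904	7	p	166	41	41
Kr	36	1.16	83.8	8	p	92	184	209
Rb	37	2.2	85.468	1	s	112	46	176
Sr	38	1.95	87.62	2	s	0	255	0
Y	39	1.9	88.906	NA	d	148	255	255
Zr	40	1.75	91.224	NA	d	148	224	224
Nb	41	1.64	92.906	NA	d	115	194	201
Mo	42	1.54	95.94	NA	d	84	181	181
Tc	43	1.47	98.0	NA	d	59	158	158
Ru	44	1.46	101.07	NA	d	36	143	143
Rh	45	1.42	102.906	NA	d	10	125	140
Pd	46	1.39	106.42	NA	d	0	105	133
Ag	47	1.45	107.868	NA	d	192	192	192
Cd	48	1.44	112.412	NA	d	255	217	143
In	49	1.42	114.818	3	p	166	117	115
Sn	50	1.39	118.711	4	p	102	128	128
Sb	51	1.39	121.76	5	p	158	99	181
Te	52	1.38	127.6	6	p	212	122	0
I	53	1.39	126.904	7	p	148	0	148
Xe	54	1.4	131.29	8	p	66	158	176
Cs	55	2.44	132.905	1	s	87	23	143
Ba	56	2.15	137.328	2	s	0	201	0
La	57	2.07	138.906	NA	d	112	212	255
Ce	58	2.04	140.116	NA	f	255	255	199
Pr	59	2.03	140.908	NA	f	217	255	199
Nd	60	2.01	144.24	NA	f	199	255	199
Pm	61	1.99	145.0	NA	f	163	255	199
Sm	62	1.98	150.36	NA	f	143	255	199
Eu	63	1.98	151.964	NA	f	97	255	199
Gd	64	1.96	157.25	NA	f	69	255	199
Tb	65	1.94	158.925	NA	f	48	255	199
Dy	66	1.92	162.5	NA	f	31	255	199
Ho	67	1.92	164.93	NA	f	0	255	156
Er	68	1.89	167.26	NA	f	0	230	117
Tm	69	1.9	168.934	NA	f	0	212	82
Yb	70	1.87	173.04	NA	f	0	191	56
Lu	71	1.87	174.967	NA	f	0	171	36
Hf	72	1.75	178.49	NA	d	77	194	255
Ta	73	1.7	180.948	NA	d	77	166	255
W	74	1.62	183.84	NA	d	33	148	214
Re	75	1.51	186.207	NA	d	38	125	171
Os	76	1.44	190.23	NA	d	38	102	150
Ir	77	1.41	192.217	NA	d	23	84	135
Pt	78	1.36	195.078	NA	d	208	208	224
Au	79	1.36	196.967	NA	d	255	209	35
Hg	80	1.32	200.59	NA	d	184	184	208
Tl	81	1.45	204.383	3	p	166	84	77
Pb	82	1.46	207.2	4	p	87	89	97
Bi	83	1.48	208.98	5	p	158	79	181
Po	84	1.4	209.0	6	p	171	92	0
At	85	1.5	210.0	7	p	117	79	69
Rn	86	1.5	222.0	8	p	66	130	150
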