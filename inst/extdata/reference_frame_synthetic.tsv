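# Reference binding-domain frame for standardization (SYNTHETIC geometry).
# Sequences: HLA-DR1 binding domain (alpha-1 pos 5-78, beta-1 pos 5-91)
# and the 13-residue peptide at harmonized positions 308-320.
# Calpha coordinates are a constructed groove, not crystallographic.
chain	pos	resname	x	y	z
A	5	HIS	-54.750	5.401	2.265
A	6	VAL	-53.250	3.639	-0.787
A	7	ILE	-51.750	6.950	-1.992
A	8	ILE	-50.250	7.562	1.478
A	9	GLN	-48.750	4.038	1.478
A	10	ALA	-47.250	4.650	-1.992
A	11	GLU	-45.750	7.961	-0.787
A	12	PHE	-44.250	6.199	2.265
A	13	TYR	-42.750	3.500	0.000
A	14	LEU	-41.250	6.199	-2.265
A	15	ASN	-39.750	7.961	0.787
A	16	PRO	-38.250	4.650	1.992
A	17	ASP	-36.750	4.038	-1.478
A	18	GLN	-35.250	7.562	-1.478
A	19	SER	-33.750	6.950	1.992
A	20	GLY	-32.250	3.639	0.787
A	21	GLU	-30.750	5.401	-2.265
A	22	PHE	-29.250	8.100	-0.000
A	23	MET	-27.750	5.401	2.265
A	24	PHE	-26.250	3.639	-0.787
A	25	ASP	-24.750	6.950	-1.992
A	26	PHE	-23.250	7.562	1.478
A	27	ASP	-21.750	4.038	1.478
A	28	GLY	-20.250	4.650	-1.992
A	29	ASP	-18.750	7.961	-0.787
A	30	GLU	-17.250	6.199	2.265
A	31	ILE	-15.750	3.500	-0.000
A	32	PHE	-14.250	6.199	-2.265
A	33	HIS	-12.750	7.961	0.787
A	34	VAL	-11.250	4.650	1.992
A	35	ASP	-9.750	4.038	-1.478
A	36	MET	-8.250	7.562	-1.478
A	37	ALA	-6.750	6.950	1.992
A	38	LYS	-5.250	3.639	0.787
A	39	LYS	-3.750	5.401	-2.265
A	40	GLU	-2.250	8.100	-0.000
A	41	THR	-0.750	5.401	2.265
A	42	VAL	0.750	3.639	-0.787
A	43	TRP	2.250	6.950	-1.992
A	44	ARG	3.750	7.562	1.478
A	45	LEU	5.250	4.038	1.478
A	46	GLU	6.750	4.650	-1.992
A	47	GLU	8.250	7.961	-0.787
A	48	PHE	9.750	6.199	2.265
A	49	GLY	11.250	3.500	-0.000
A	50	ARG	12.750	6.199	-2.265
A	51	PHE	14.250	7.961	0.787
A	52	ALA	15.750	4.650	1.992
A	53	SER	17.250	4.038	-1.478
A	54	PHE	18.750	7.562	-1.478
A	55	GLU	20.250	6.950	1.992
A	56	ALA	21.750	3.639	0.787
A	57	GLN	23.250	5.401	-2.265
A	58	GLY	24.750	8.100	0.000
A	59	ALA	26.250	5.401	2.265
A	60	LEU	27.750	3.639	-0.787
A	61	ALA	29.250	6.950	-1.992
A	62	ASN	30.750	7.562	1.478
A	63	ILE	32.250	4.038	1.478
A	64	ALA	33.750	4.650	-1.992
A	65	VAL	35.250	7.961	-0.787
A	66	ASP	36.750	6.199	2.265
A	67	LYS	38.250	3.500	0.000
A	68	ALA	39.750	6.199	-2.265
A	69	ASN	41.250	7.961	0.787
A	70	LEU	42.750	4.650	1.992
A	71	GLU	44.250	4.038	-1.478
A	72	ILE	45.750	7.562	-1.478
A	73	MET	47.250	6.950	1.992
A	74	THR	48.750	3.639	0.787
A	75	LYS	50.250	5.401	-2.265
A	76	ARG	51.750	8.100	-0.000
A	77	SER	53.250	5.401	2.265
A	78	ASN	54.750	3.639	-0.787
B	5	PRO	-64.500	-6.199	2.265
B	6	ARG	-63.000	-7.961	-0.787
B	7	PHE	-61.500	-4.650	-1.992
B	8	LEU	-60.000	-4.038	1.478
B	9	TRP	-58.500	-7.562	1.478
B	10	GLN	-57.000	-6.950	-1.992
B	11	LEU	-55.500	-3.639	-0.787
B	12	LYS	-54.000	-5.401	2.265
B	13	PHE	-52.500	-8.100	0.000
B	14	GLU	-51.000	-5.401	-2.265
B	15	CYS	-49.500	-3.639	0.787
B	16	HIS	-48.000	-6.950	1.992
B	17	PHE	-46.500	-7.562	-1.478
B	18	PHE	-45.000	-4.038	-1.478
B	19	ASN	-43.500	-4.650	1.992
B	20	GLY	-42.000	-7.961	0.787
B	21	THR	-40.500	-6.199	-2.265
B	22	GLU	-39.000	-3.500	-0.000
B	23	ARG	-37.500	-6.199	2.265
B	24	VAL	-36.000	-7.961	-0.787
B	25	ARG	-34.500	-4.650	-1.992
B	26	LEU	-33.000	-4.038	1.478
B	27	LEU	-31.500	-7.562	1.478
B	28	GLU	-30.000	-6.950	-1.992
B	29	ARG	-28.500	-3.639	-0.787
B	30	CYS	-27.000	-5.401	2.265
B	31	ILE	-25.500	-8.100	-0.000
B	32	TYR	-24.000	-5.401	-2.265
B	33	ASN	-22.500	-3.639	0.787
B	34	GLN	-21.000	-6.950	1.992
B	35	GLU	-19.500	-7.562	-1.478
B	36	GLU	-18.000	-4.038	-1.478
B	37	SER	-16.500	-4.650	1.992
B	38	VAL	-15.000	-7.961	0.787
B	39	ARG	-13.500	-6.199	-2.265
B	40	PHE	-12.000	-3.500	-0.000
B	41	ASP	-10.500	-6.199	2.265
B	42	SER	-9.000	-7.961	-0.787
B	43	ASP	-7.500	-4.650	-1.992
B	44	VAL	-6.000	-4.038	1.478
B	45	GLY	-4.500	-7.562	1.478
B	46	GLU	-3.000	-6.950	-1.992
B	47	TYR	-1.500	-3.639	-0.787
B	48	ARG	0.000	-5.401	2.265
B	49	ALA	1.500	-8.100	-0.000
B	50	VAL	3.000	-5.401	-2.265
B	51	THR	4.500	-3.639	0.787
B	52	GLU	6.000	-6.950	1.992
B	53	LEU	7.500	-7.562	-1.478
B	54	GLY	9.000	-4.038	-1.478
B	55	ARG	10.500	-4.650	1.992
B	56	PRO	12.000	-7.961	0.787
B	57	ASP	13.500	-6.199	-2.265
B	58	ALA	15.000	-3.500	0.000
B	59	GLU	16.500	-6.199	2.265
B	60	TYR	18.000	-7.961	-0.787
B	61	TRP	19.500	-4.650	-1.992
B	62	ASN	21.000	-4.038	1.478
B	63	SER	22.500	-7.562	1.478
B	64	GLN	24.000	-6.950	-1.992
B	65	LYS	25.500	-3.639	-0.787
B	66	ASP	27.000	-5.401	2.265
B	67	LEU	28.500	-8.100	0.000
B	68	LEU	30.000	-5.401	-2.265
B	69	GLU	31.500	-3.639	0.787
B	70	GLN	33.000	-6.950	1.992
B	71	ARG	34.500	-7.562	-1.478
B	72	ARG	36.000	-4.038	-1.478
B	73	ALA	37.500	-4.650	1.992
B	74	ALA	39.000	-7.961	0.787
B	75	VAL	40.500	-6.199	-2.265
B	76	ASP	42.000	-3.500	-0.000
B	77	THR	43.500	-6.199	2.265
B	78	TYR	45.000	-7.961	-0.787
B	79	CYS	46.500	-4.650	-1.992
B	80	ARG	48.000	-4.038	1.478
B	81	HIS	49.500	-7.562	1.478
B	82	ASN	51.000	-6.950	-1.992
B	83	TYR	52.500	-3.639	-0.787
B	84	GLY	54.000	-5.401	2.265
B	85	VAL	55.500	-8.100	0.000
B	86	GLY	57.000	-5.401	-2.265
B	87	GLU	58.500	-3.639	0.787
B	88	SER	60.000	-6.950	1.992
B	89	PHE	61.500	-7.562	-1.478
B	90	THR	63.000	-4.038	-1.478
B	91	VAL	64.500	-4.650	1.992
C	308	PRO	-21.000	0.000	0.000
C	309	LYS	-17.500	0.000	0.000
C	310	TYR	-14.000	0.000	0.000
C	311	VAL	-10.500	0.000	0.000
C	312	LYS	-7.000	0.000	0.000
C	313	GLN	-3.500	0.000	0.000
C	314	ASN	0.000	0.000	0.000
C	315	THR	3.500	0.000	0.000
C	316	LEU	7.000	0.000	0.000
C	317	LYS	10.500	0.000	0.000
C	318	LEU	14.000	0.000	0.000
C	319	ALA	17.500	0.000	0.000
C	320	THR	21.000	0.000	0.000
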