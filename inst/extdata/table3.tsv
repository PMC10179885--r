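peak_no	printed_id	rt_min	cn	db	geometry	rel_area_pct
1	1	6.45	49	0		5.9
2	2	6.45	48	0		1.4
3	3	6.48	47	0		11.3
4	4	6.48	46	0		2.0
5	5	6.50	45	0		11.3
6	6	6.50	44	0		2.0
7	7	6.50	43	0		7.1
8	8	6.50	42	0		1.9
9	9	6.50	41	0		2.4
10	10	6.50	40	0		1.3
11	11	6.50	39	0		1.7
12	12	6.50	38	0		1.2
13	13	6.50	37	0		1.2
14	14	6.50	36	0		1.1
15	15	6.52	35	0		2.0
16	16	6.52	34	0		1.6
17	17	6.54	33	0		5.4
18	18	6.54	32	0		6.0
19	19	6.56	31	0		5.4
20	20	6.56	30	0		13.1
21	21	6.56	29	0		4.8
22	22	6.56	28	0		4.8
23	23	6.56	27	0		2.9
24	24	6.56	26	0		2.3
25	25	30.28	47	1	cis	3.9
26	26	30.34	46	1	cis	0.6
27	27	30.36	45	1	cis	5.8
28	28	30.50	44	1	cis	0.8
29	29	30.50	43	1	cis	5.1
30	30	30.67	42	1	cis	11.7
31	31	30.73	40	1	cis	10.7
32	32	30.86	41	1	cis	4.1
33	33	30.86	40	1	cis	8.7
34	34	30.93	38	1	cis	7.2
35	35	30.95	39	1	cis	12.1
36	36	31.04	38	1	cis	5.0
37	37	31.17	37	1	cis	11.8
38	38	31.19	36	1	cis	2.4
39	39	31.30	35	1	cis	1.6
40	40	31.38	34	1	cis	0.8
41	41	31.46	33	1	cis	0.5
42	42	31.46	32	1	cis	1.2
43	43	31.61	31	1	cis	2.0
44	44	31.69	30	1	cis	0.4
45	45	31.73	28	1	cis	0.4
46	46	31.77	29	1	cis	2.1
47	47	31.92	27	1	cis	1.3
48	48	55.38	45	2	cis	0.6
49	49	62.18	41	2	cis	0.1
50	50	62.77	39	2	cis	0.2
51	51	62.93	41	2	cis	0.4
52	52	63.53	43	2	cis	0.1
53	53	63.60	39	2	cis	1.6
54	54	63.75	45	2	cis	0.2
55	55	63.91	41	2	cis	1.1
56	56	64.25	37	2	cis	0.2
57	57	64.34	43	2	cis	0.3
58	58	64.36	39	2	cis	1.4
59	59	64.51	45	2	cis	0.4
60	60	64.80	41	2	cis	0.4
61	61	65.03	37	2	cis	0.3
62	62	65.05	43	2	cis	0.9
63	63	65.07	46	2	cis	0.3
64	64	65.22	39	2	cis	0.5
65	65	65.55	44	2	cis	0.5
66	66	65.71	37	2	cis	0.1
67	67	65.71	41	2	cis	1.8
68	68	65.86	43	2	cis	1.7
69	69	66.17	39	2	cis	0.4
70	70	66.26	42	2	cis	0.6
71	71	66.26	46	2	cis	1.0
72	72	66.42	41	2	cis	3.9
73	73	66.48	45	2	cis	1.7
74	74	66.82	44	2	cis	2.3
75	75	66.84	40	2	cis	0.2
76	76	67.12	43	2	cis	8.0
77	77	67.16	39	2	cis	1.7
78	78	67.45	37	2	cis	0.1
79	79	67.45	42	2	cis	3.1
80	80	67.63	41	2	cis	22.8
81	81	67.97	40	2	cis	1.7
82	82	68.27	39	2	cis	10.4
83	83	68.47	38	2	cis	0.1
84	84	68.81	38	2	cis	0.1
85	85	68.85	46	2	cis	0.6
86	86	69.12	37	2	cis	0.8
87	87	69.43	45	2	cis	0.2
88	88	69.64	44	2	cis	1.7
89	89	70.13	43	2	cis	0.8
90	90	70.37	42	2	cis	18.1
91	91	70.73	41	2	cis	2.5
92	92	70.86	40	2	cis	0.4
93	93	71.23	39	2	cis	2.6
94	94	71.32	40	2	cis	0.6
95	95	71.74	38	2	cis	0.2
96	96	71.90	37	2	cis	0.2
97	97	99.90	47	3	cis	0.6
98	98	100.73	47	3	cis	0.6
99	99	101.33	45	3	cis	1.3
100	100	101.53	47	3	cis	3.0
101	101	102.12	45	3	cis	1.7
102	102	102.58	47	3	cis	0.9
103	103	103.01	45	3	cis	7.5
104	104	103.50	43	3	cis	0.9
105	105	103.69	44	3	cis	0.6
106	106	103.84	45	3	cis	4.2
107	107	104.44	47	3	cis	0.4
108	108	104.55	43	3	cis	22.0
109	109	104.55	44	3	cis	0.4
110	110	104.94	45	3	cis	1.2
111	111	105.10	41	3	cis	0.6
112	112	105.18	42	3	cis	0.6
113	113	105.20	43	3	cis	13.0
114	114	105.49	47	3	cis	0.7
115	115	105.92	45	3	cis	0.5
116	116	106.03	42	3	cis	0.5
117	117	106.23	43	3	cis	1.6
118	118	106.83	41	3	cis	13.9
119	119	106.97	45	3	cis	1.9
120	120	107.30	49	3	cis	0.4
121	121	107.52	43	3	cis	1.9
122	122	107.86	41	3	cis	2.6
123	123	107.90	45	3	cis	0.8
124	124	108.60	43	3	cis	3.9
125	125	108.94	39	3	cis	0.4
126	126	108.97	41	3	cis	0.5
127	127	109.43	39	3	cis	0.3
128	128	109.52	43	3	cis	1.4
129	129	110.31	41	3	cis	4.2
130	130	110.77	43	3	cis	0.4
131	131	111.37	41	3	cis	2.0
132	132	112.33	41	3	cis	0.9
133	133	113.05	39	3	cis	0.7
134	134	113.76	41	3	cis	0.3
135	135	114.17	39	3	cis	0.5
136	136	114.21	43	3	cis	0.2
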