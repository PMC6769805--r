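residue	name	coupled	mu_phi_1	mu_psi_1	kappa_phi	kappa_psi
1	I	0	-128.1	122	12	12
2	Q	0	-138.9	132	12	12
3	R	0	-140.3	122.9	12	12
4	T	0	-122.7	140.7	12	12
5	P	0	-155.8	138	12	12
6	K	0	-96.8	141.6	12	12
7	I	0	-119.7	134.1	12	12
8	Q	0	-130.7	121	12	12
9	V	0	-112.5	141.9	12	12
10	Y	0	-110.9	121.6	12	12
11	S	0	-102.9	142.4	12	12
12	R	0	-119.7	164.5	12	12
13	H	0	-124.2	134.2	12	12
14	P	0	-116.5	127.6	12	12
15	A	0	-110.7	147.4	12	12
16	E	0	-115.8	115.6	12	12
17	N	0	-128.5	135.4	12	12
18	G	0	-111	141.7	12	12
19	K	0	-128.6	149.4	12	12
20	S	0	-116.7	136.9	12	12
21	N	0	-165.1	132.7	12	12
22	F	0	-95.8	158.7	12	12
23	L	0	-101	138.8	12	12
24	N	0	-118.6	110.1	12	12
25	C	0	-123.6	136.9	12	12
26	Y	0	-127	138.7	12	12
27	V	0	-121.6	135.9	12	12
28	S	0	-131.3	107.4	12	12
29	G	0	-135.6	121.5	12	12
30	F	0	-91.2	148.9	12	12
31	H	0	-102.6	126.1	12	12
32	P	0	-88.1	130.1	12	12
33	S	0	-137.6	132.6	12	12
34	D	0	-109.7	137.7	12	12
35	I	0	-112.7	118.9	12	12
36	E	0	-119.1	149.2	12	12
37	V	1	-111.3	127	12	12
38	D	0	-120.9	120.9	12	12
39	L	0	-98.3	122.5	12	12
40	L	0	-116.6	153.4	12	12
41	K	1	-114.4	121.1	12	12
42	N	0	-128.1	142.1	12	12
43	G	0	-153.5	147.2	12	12
44	E	0	-103.9	120.2	12	12
45	R	0	-122.6	136.1	12	12
46	I	0	-127.5	146	12	12
47	E	0	-141.1	135.6	12	12
48	K	0	-108.5	146	12	12
49	V	0	-133.2	106.9	12	12
50	E	0	-105.4	155.2	12	12
51	H	0	-113.1	134.1	12	12
52	S	0	-135.8	123.4	12	12
53	D	1	-112.8	135.8	12	12
54	L	0	-126.1	111.2	12	12
55	S	1	-104.7	122.4	12	12
56	F	0	-120.3	130.7	12	12
57	S	0	-126.8	143.1	12	12
58	K	0	-117	152.2	12	12
59	D	0	-135.4	143.9	12	12
60	W	0	-135	150.6	12	12
61	S	0	-132.3	138.5	12	12
62	F	0	-121.1	148	12	12
63	Y	0	-101	112.7	12	12
64	L	1	-96.2	127.2	12	12
65	L	1	-124.8	177.1	12	12
66	Y	0	-137.8	137.6	12	12
67	Y	0	-90.8	145.2	12	12
68	T	0	-102.2	162.7	12	12
69	E	0	-107.1	155.7	12	12
70	F	0	-138.5	114	12	12
71	T	0	-123.5	119.2	12	12
72	P	0	-108.5	163.9	12	12
73	T	0	-112.8	112.7	12	12
74	E	0	-115.1	146.4	12	12
75	K	0	-132.2	140.4	12	12
76	D	1	-93.2	111.5	12	12
77	E	0	-146.5	119.2	12	12
78	Y	0	-126.1	152	12	12
79	A	0	-112.5	126.1	12	12
80	C	0	-121.1	144	12	12
81	R	0	-123.2	135.8	12	12
82	V	0	-143	105.5	12	12
83	N	0	-112.2	156.1	12	12
84	H	0	-153.2	176.3	12	12
85	V	0	-109.8	146.3	12	12
86	T	0	-94.6	117.5	12	12
87	L	0	-100.1	111.1	12	12
88	S	0	-114.2	171.3	12	12
89	Q	0	-115.3	133.7	12	12
90	P	0	-115.4	115.6	12	12
91	K	0	-106.9	134.5	12	12
92	I	0	-115.5	138.4	12	12
93	V	0	-107.5	135.6	12	12
94	K	0	-115.1	125.4	12	12
95	W	0	-149.1	162.1	12	12
96	D	0	-108.7	151.3	12	12
97	R	0	-129	148.5	12	12
98	D	0	-102.5	140.7	12	12
99	M	0	-137.9	149	12	12
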