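residue	name	traceable	slope_H	slope_N	amp_H	amp_N	dH0	dN0	mut_offset_H	mut_offset_N	r2	kex_per_min
1	I	0	0.00011634	-8.0276e-05	-0.00032448	-0.013937	7.92	114.79	0	0	8	NA
2	Q	0	-0.000197	-0.0018006	-0.0044036	0.012178	8.401	128.24	0	0	8	NA
3	R	1	-6.7386e-07	-0.0010226	-0.005919	0.005422	9.333	109.74	0	0	8	NA
4	T	1	7.255e-05	-0.0010813	0.0059609	-0.0062154	8.639	110.56	0	0	8	NA
5	P	0	-0.00031595	-0.00049187	-0.0017201	0.0082421	8.258	122.77	0	0	8	NA
6	K	1	8.7996e-05	0.00077268	-0.0061766	0.013247	8.821	117.22	0	0	8	NA
7	I	1	-0.00014058	0.00066249	-0.0037223	0.0088931	9.462	127.65	0	0	8	NA
8	Q	1	-7.5753e-05	0.0012451	0.0069088	0.013373	8.59	110.64	0	0	8	NA
9	V	1	-0.00022802	0.00092807	0.0024518	0.042619	8.626	122.36	0	0	8	NA
10	Y	1	-0.00014908	0.0017016	0.005522	-0.01505	9.025	122.15	0	0	8	NA
11	S	1	-0.0002745	0.0011576	-0.002955	-0.00045575	8.886	124.78	0	0	8	NA
12	R	1	-0.00034292	0.0016654	0.0017212	-0.0082092	8.793	125.72	0	0	8	NA
13	H	1	-0.00011846	-0.0013431	0.0037942	0.018289	7.865	126.64	0	0	8	NA
14	P	0	1.3754e-05	-0.0013376	0.0027642	-0.017417	8.618	128.78	0	0	8	NA
15	A	1	-9.3313e-05	0.002579	0.0049023	0.0075691	8.058	113.26	0	0	8	NA
16	E	1	0.00028738	0.0013128	0.0029309	0.019219	8.232	114.01	0	0	8	NA
17	N	0	-0.00027896	0.0013474	-0.00091822	-0.0012249	7.666	110.35	0	0	8	NA
18	G	0	9.0602e-05	0.0015064	-0.0024913	-0.0035002	8.359	124.28	0	0	8	NA
19	K	1	-0.00019373	-0.0038117	-0.00063535	-0.041739	8.449	123.72	0	0	8	NA
20	S	1	-0.00055311	-0.00067288	0.0022608	-0.02102	7.871	114.27	0	0	8	NA
21	N	1	4.1846e-05	0.0014797	-0.0019166	0.0021827	8.177	127.79	0	0	8	0.000126
22	F	1	-0.00062012	-0.0015378	-0.0024854	-0.0074514	8.51	121.01	0	0	8	0.00085
23	L	1	-5.9733e-05	0.00033238	-0.0058729	-0.035671	7.61	121.07	0	0	8	0.00166
24	N	1	-1.3942e-05	-0.0013095	0.00053884	0.0034298	7.554	126.95	0	0	8	0.0013
25	C	1	0.00032228	0.00055568	0.0058752	0.025957	8.475	122.7	0	0	8	0.0042
26	Y	1	0.00019359	-0.00019277	-0.0019075	0.0047399	7.783	121.04	0	0	8	0.000161
27	V	1	-0.00022329	0.001495	0.0041952	0.00071037	8.239	114.5	0	0	8	0.000406
28	S	1	-0.00037729	0.0002187	-0.0035848	-1.9273e-05	8.829	121.34	0	0	8	0.00133
29	G	1	-0.00013555	0.002314	-0.0050444	0.00091927	7.686	113.48	0	0	8	0.00185
30	F	1	-0.00012144	-0.00054981	0.0011742	0.0090048	9.471	108.8	0	0	8	0.00188
31	H	1	-0.0002355	-0.00058303	-0.0022427	0.0072286	8.724	127.17	0	0	8	NA
32	P	0	0.00043126	0.0023356	0.002064	0.0050832	7.522	112.3	0	0	8	NA
33	S	1	0.00043797	0.00016218	-0.0018938	0.032537	8.183	109.06	0	0	8	NA
34	D	1	-0.0003197	-0.0011024	0.0007142	-0.00088182	7.738	128.07	0	0	8	NA
35	I	1	0.00035499	0.00077298	-0.002251	-0.0038991	8.929	115.48	0	0	8	NA
36	E	1	0.00036978	5.3337e-05	-0.00075628	-0.022035	7.677	113.12	0	0	8	0.000466
37	V	1	0.0005625	-0.0033364	-0.0018779	-0.022499	8.852	114.65	0	0	8	0.000102
38	D	1	0.00024041	-0.00015225	0.0030815	-0.01415	7.545	108.4	0	0	8	0.00011
39	L	1	6.277e-05	0.00025228	0.0079412	0.0048061	8.308	127.14	0	0	8	0.00354
40	L	1	-0.00010242	-0.00018324	0.0018715	0.005503	7.61	129.05	0	0	8	0.000239
41	K	1	-5.0567e-05	-0.0022835	0.0036912	-0.0097557	7.565	120.78	0	0	8	0.00559
42	N	1	-0.00013949	0.00094236	0.0014356	0.018741	7.648	116.85	0	0	8	NA
43	G	1	0.00021262	-0.0011031	0.0052374	0.025456	8.1	126.97	0	0	8	NA
44	E	1	-6.296e-06	-0.0022087	-0.00097171	-0.030689	7.955	113.15	0	0	8	NA
45	R	1	1.4847e-06	0.0022326	-8.4203e-05	-0.018035	8.648	120.79	0	0	8	NA
46	I	1	5.1608e-05	0.00061951	-0.0052701	0.0059581	9.101	125.58	0	0	8	NA
47	E	0	-0.00026515	0.0018679	-0.002108	0.039449	8.235	129.71	0	0	8	NA
48	K	1	-0.00041938	-0.0017431	-0.0062686	-0.032608	9.075	111.3	0	0	8	NA
49	V	1	3.6389e-05	-0.0014948	0.00014275	0.0063223	8.681	113.52	0	0	8	NA
50	E	1	0.00044781	0.0018064	0.00094367	-0.015442	8.503	112.49	0	0	8	NA
51	H	1	-5.5963e-05	0.0015314	-0.0095173	-0.012322	7.745	128.83	0	0	8	NA
52	S	1	6.1752e-05	0.0016822	0.000299	-0.017816	8.15	117.59	0	0	8	NA
53	D	1	0.00048016	0.00034573	-0.0060925	-0.014971	8.604	128.88	0	0	8	NA
54	L	1	-5.7085e-05	0.00051979	-0.0011138	-0.047022	8.048	122.87	0	0	8	NA
55	S	1	7.5204e-05	-0.00019256	-0.00053501	-0.013631	8.076	123.34	0	0	8	NA
56	F	1	-4.4609e-05	0.002459	-0.0022503	-0.015281	9.22	112.58	0	0	8	NA
57	S	1	4.4852e-05	0.0010626	0.0047101	0.011989	9.13	122.19	0	0	8	NA
58	K	1	-4.3567e-05	0.0013794	0.00049396	-0.006893	8.974	117.1	0	0	8	NA
59	D	0	-0.00014236	-0.0019653	-0.004774	-0.024829	8.308	122.77	0	0	8	NA
60	W	0	-0.00021506	0.00037346	-0.0063614	0.03249	8.613	121.36	0	0	8	NA
61	S	1	-0.00026413	-0.0002117	-0.00083096	0.0079524	9.265	122.19	0	0	8	NA
62	F	1	0.00075092	-0.0016579	-0.00049826	0.018251	7.583	122.96	0	0	8	0.000394
63	Y	1	-0.00029457	-0.00020856	0.0020553	-0.034673	9.284	122.67	0	0	8	0.000286
64	L	1	-0.00018235	0.0011017	-0.0016882	-0.014175	7.697	122.65	0	0	8	0.0028
65	L	1	-0.00036721	-0.00059856	-0.00083786	0.028196	7.81	110.9	0	0	8	0.000124
66	Y	1	-0.00021966	-0.00080648	-0.0020918	-0.004426	8.298	113.92	0	0	8	0.000639
67	Y	1	0.00073875	-0.00049821	0.00048321	-0.017373	8.872	116.91	0	0	8	0.000603
68	T	1	-3.7036e-05	-0.00058901	-0.00018502	0.028667	7.626	119.48	0	0	8	0.000146
69	E	1	-7.2858e-05	-3.0965e-05	0.003956	0.011012	8.944	126	0	0	8	0.000588
70	F	1	-0.00019597	0.0020659	-0.0016426	0.02339	8.194	111.95	0	0	8	0.00023
71	T	1	0.00044117	0.00017274	0.0062301	-0.0031787	8.986	110.9	0	0	8	NA
72	P	0	-0.00023843	-0.0015491	-0.00055396	-0.0019262	8.763	115.52	0	0	8	NA
73	T	1	-0.00011037	-0.00089772	0.0019221	0.0049497	7.82	124.35	0	0	8	NA
74	E	1	-0.00011083	0.0019653	-0.00051106	0.017618	8.03	120.35	0	0	8	NA
75	K	1	-0.00038776	0.00022913	-0.00018929	-0.0050924	8.357	111.04	0	0	8	NA
76	D	1	-0.00024697	0.0017537	0.0045105	-0.00097709	8.845	127.88	0	0	8	NA
77	E	1	0.00020963	0.00043495	0.0043624	0.0094306	8.142	122.53	0	0	8	NA
78	Y	1	-0.0003177	-0.001254	-0.002934	-0.016025	8.537	116.92	0	0	8	0.000141
79	A	1	-0.00014948	-0.001057	-0.0038148	0.039284	8.769	127.09	0	0	8	0.000978
80	C	1	0.00052397	-0.002341	0.0010456	-0.025259	8.096	123.09	0	0	8	0.000116
81	R	1	-0.00016373	0.00047642	8.8862e-05	0.0014737	8.609	112.93	0	0	8	0.000138
82	V	1	0.00036573	-0.0022954	-0.00061588	-0.032159	9.341	122.19	0	0	8	0.00382
83	N	1	-0.00045001	-0.0011916	0.0045014	0.01089	8.396	111	0	0	8	0.000137
84	H	0	-0.00039517	-0.001329	-0.0062599	-0.014666	7.678	129.04	0	0	8	NA
85	V	0	0.00022128	-0.0015276	0.0023455	0.031067	7.998	112.57	0	0	8	NA
86	T	1	-0.00010791	0.0014598	0.00032742	0.038029	8.478	113.63	0	0	8	NA
87	L	1	-0.00017183	-0.00020643	-0.0037274	0.019398	8.482	109.85	0	0	8	NA
88	S	1	-0.00015984	-0.0010259	0.00025218	-0.029525	7.879	128.89	0	0	8	NA
89	Q	1	0.00042115	-0.0023293	-0.0058191	-0.029493	9.166	112.37	0	0	8	NA
90	P	0	0.00050239	0.00076193	0.00059005	-0.025575	7.535	117.62	0	0	8	NA
91	K	0	0.00052793	-0.0012661	-0.0018778	-0.0054922	7.922	114.03	0	0	8	NA
92	I	1	0.00033479	0.0016514	0.003926	0.029279	8.703	121.25	0	0	8	NA
93	V	1	-4.4935e-05	2.7602e-05	0.00052825	-0.033442	8.975	117.8	0	0	8	NA
94	K	1	-0.00023398	0.0011501	0.0020658	-0.02158	8.463	127.6	0	0	8	NA
95	W	1	-1.95e-05	0.00083548	-0.008351	-0.021175	8.985	124.01	0	0	8	NA
96	D	1	-0.00034765	-0.0012242	0.0051097	-0.03121	8.75	118.19	0	0	8	NA
97	R	1	0.00034833	6.7799e-05	-0.00046593	-0.018244	8.16	129.4	0	0	8	NA
98	D	0	0.00031249	-0.00039548	0.0016657	0.033765	7.583	111.64	0	0	8	NA
99	M	0	0.00035793	-0.00012128	-0.0016739	0.0090646	7.764	129.66	0	0	8	NA
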