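residue	name	traceable	slope_H	slope_N	amp_H	amp_N	dH0	dN0	mut_offset_H	mut_offset_N	r2	kex_per_min
1	I	0	0.00011634	-8.0276e-05	-0.0055722	-0.028653	7.92	114.79	0	0	8	NA
2	Q	0	-0.000197	-0.0018006	0.0013207	-0.020519	8.401	128.24	0	0	8	NA
3	R	1	-6.7386e-07	-0.0010226	-0.0090502	-0.01358	9.333	109.74	0	0	8	NA
4	T	1	7.255e-05	-0.0010813	-0.0022669	0.0086844	8.639	110.56	0	0	8	NA
5	P	0	-0.00031595	-0.00049187	0.0042966	0.030719	8.258	122.77	0	0	8	NA
6	K	1	8.7996e-05	0.00077268	0.11631	0.49355	8.821	117.22	0	0	8	NA
7	I	1	-0.00014058	0.00066249	0.086738	-0.76332	9.462	127.65	0	0	8	NA
8	Q	1	-7.5753e-05	0.0012451	0.12633	0.58391	8.59	110.64	0	0	8	NA
9	V	1	-0.00022802	0.00092807	0.19424	-0.62908	8.626	122.36	0	0	8	NA
10	Y	1	-0.00014908	0.0017016	0.18782	0.5455	9.025	122.15	0	0	8	NA
11	S	1	-0.0002745	0.0011576	0.091101	0.64648	8.886	124.78	0	0	8	NA
12	R	1	-0.00034292	0.0016654	-0.0013792	-0.013829	8.793	125.72	0	0	8	NA
13	H	1	-0.00011846	-0.0013431	0.0015979	0.028945	7.865	126.64	0	0	8	NA
14	P	0	1.3754e-05	-0.0013376	0.0017324	-0.030643	8.618	128.78	0	0	8	NA
15	A	1	-9.3313e-05	0.002579	-0.00089957	-0.0041327	8.058	113.26	0	0	16	NA
16	E	1	0.00028738	0.0013128	-0.00035491	-0.025728	8.232	114.01	0	0	16	NA
17	N	0	-0.00027896	0.0013474	-0.001909	0.0012642	7.666	110.35	0	0	16	NA
18	G	0	9.0602e-05	0.0015064	0.0034202	-0.009602	8.359	124.28	0	0	16	NA
19	K	1	-0.00019373	-0.0038117	-0.0028528	-0.035421	8.449	123.72	0	0	16	NA
20	S	1	-0.00055311	-0.00067288	0.0098734	-0.0015757	7.871	114.27	0	0	8	NA
21	N	1	4.1846e-05	0.0014797	0.0012672	-0.024029	8.177	127.79	0	0	8	0.000126
22	F	1	-0.00062012	-0.0015378	0.0013555	-0.023873	8.51	121.01	0	0	8	0.00085
23	L	1	-5.9733e-05	0.00033238	-0.00070134	-0.045747	7.61	121.07	0	0	8	0.00166
24	N	1	-1.3942e-05	-0.0013095	0.0031236	-0.01036	7.554	126.95	0	0	16	0.0013
25	C	1	0.00032228	0.00055568	0.003858	0.021692	8.475	122.7	0	0	16	0.0042
26	Y	1	0.00019359	-0.00019277	-0.0055356	-0.0030646	7.783	121.04	0	0	16	0.000161
27	V	1	-0.00022329	0.001495	0.0038339	0.015508	8.239	114.5	0	0	8	0.000406
28	S	1	-0.00037729	0.0002187	0.0011436	-0.049099	8.829	121.34	0	0	8	0.00133
29	G	1	-0.00013555	0.002314	0.0068728	-0.037165	7.686	113.48	0	0	8	0.00185
30	F	1	-0.00012144	-0.00054981	-0.0060768	0.011286	9.471	108.8	0	0	8	0.00188
31	H	1	-0.0002355	-0.00058303	0.0043761	0.0060282	8.724	127.17	0	0	8	NA
32	P	0	0.00043126	0.0023356	0.0084061	-0.020806	7.522	112.3	0	0	8	NA
33	S	1	0.00043797	0.00016218	0.0036141	-0.056242	8.183	109.06	0	0	8	NA
34	D	1	-0.0003197	-0.0011024	-0.0040014	0.0046575	7.738	128.07	0	0	8	NA
35	I	1	0.00035499	0.00077298	-0.0032911	-0.020346	8.929	115.48	0	0	8	NA
36	E	1	0.00036978	5.3337e-05	0.10481	0.87548	7.677	113.12	0	0	8	0.000466
37	V	1	0.0005625	-0.0033364	0.12192	0.50754	8.852	114.65	0	0	8	0.000102
38	D	1	0.00024041	-0.00015225	0.17945	0.53856	7.545	108.4	0	0	8	0.00011
39	L	1	6.277e-05	0.00025228	0.10974	-0.67819	8.308	127.14	0	0	8	0.00354
40	L	1	-0.00010242	-0.00018324	-0.07838	0.90502	7.61	129.05	0	0	8	0.000239
41	K	1	-5.0567e-05	-0.0022835	0.12225	0.50741	7.565	120.78	0	0	8	0.00559
42	N	1	-0.00013949	0.00094236	0.0057109	-0.017433	7.648	116.85	0	0	8	NA
43	G	1	0.00021262	-0.0011031	-0.0010921	-0.035156	8.1	126.97	0	0	8	NA
44	E	1	-6.296e-06	-0.0022087	0.0014455	0.01533	7.955	113.15	0	0	16	NA
45	R	1	1.4847e-06	0.0022326	2.7224e-05	0.036556	8.648	120.79	0	0	16	NA
46	I	1	5.1608e-05	0.00061951	-0.006781	-0.001804	9.101	125.58	0	0	16	NA
47	E	0	-0.00026515	0.0018679	0.0011734	-0.02022	8.235	129.71	0	0	8	NA
48	K	1	-0.00041938	-0.0017431	0.0028857	0.0196	9.075	111.3	0	0	8	NA
49	V	1	3.6389e-05	-0.0014948	-0.0014833	0.020257	8.681	113.52	0	0	8	NA
50	E	1	0.00044781	0.0018064	-0.0047823	0.0066057	8.503	112.49	0	0	8	NA
51	H	1	-5.5963e-05	0.0015314	0.10298	-0.61294	7.745	128.83	0	0	8	NA
52	S	1	6.1752e-05	0.0016822	0.071389	-0.77684	8.15	117.59	0	0	16	NA
53	D	1	0.00048016	0.00034573	0.15301	-0.63486	8.604	128.88	0	0	16	NA
54	L	1	-5.7085e-05	0.00051979	-0.10362	-0.87562	8.048	122.87	0	0	16	NA
55	S	1	7.5204e-05	-0.00019256	-0.10475	0.9086	8.076	123.34	0	0	16	NA
56	F	1	-4.4609e-05	0.002459	0.12556	0.8756	9.22	112.58	0	0	8	NA
57	S	1	4.4852e-05	0.0010626	-0.0016236	-0.0052993	9.13	122.19	0	0	8	NA
58	K	1	-4.3567e-05	0.0013794	0.0039322	0.014864	8.974	117.1	0	0	8	NA
59	D	0	-0.00014236	-0.0019653	0.0021869	0.0029072	8.308	122.77	0	0	8	NA
60	W	0	-0.00021506	0.00037346	0.0056881	-0.014221	8.613	121.36	0	0	8	NA
61	S	1	-0.00026413	-0.0002117	0.0030501	0.0086264	9.265	122.19	0	0	8	NA
62	F	1	0.00075092	-0.0016579	-0.00088496	0.02458	7.583	122.96	0	0	8	0.000394
63	Y	1	-0.00029457	-0.00020856	-0.0013019	-0.0084466	9.284	122.67	0	0	8	0.000286
64	L	1	-0.00018235	0.0011017	0.0046691	0.031351	7.697	122.65	0	0	8	0.0028
65	L	1	-0.00036721	-0.00059856	-0.0035641	-0.011934	7.81	110.9	0	0	8	0.000124
66	Y	1	-0.00021966	-0.00080648	0.0038169	0.014008	8.298	113.92	0	0	8	0.000639
67	Y	1	0.00073875	-0.00049821	0.0050765	0.0027515	8.872	116.91	0	0	8	0.000603
68	T	1	-3.7036e-05	-0.00058901	0.007904	-0.034853	7.626	119.48	0	0	8	0.000146
69	E	1	-7.2858e-05	-3.0965e-05	0.0042682	0.023738	8.944	126	0	0	8	0.000588
70	F	1	-0.00019597	0.0020659	-0.0061486	-0.044059	8.194	111.95	0	0	8	0.00023
71	T	1	0.00044117	0.00017274	0.0084441	-0.010861	8.986	110.9	0	0	8	NA
72	P	0	-0.00023843	-0.0015491	0.0015737	0.010834	8.763	115.52	0	0	8	NA
73	T	1	-0.00011037	-0.00089772	-0.003512	0.017633	7.82	124.35	0	0	8	NA
74	E	1	-0.00011083	0.0019653	-0.0018125	-0.023111	8.03	120.35	0	0	8	NA
75	K	1	-0.00038776	0.00022913	0.0012262	-0.01253	8.357	111.04	0	0	8	NA
76	D	1	-0.00024697	0.0017537	-6.478e-05	0.020417	8.845	127.88	0	0	8	NA
77	E	1	0.00020963	0.00043495	-0.0043893	0.020076	8.142	122.53	0	0	8	NA
78	Y	1	-0.0003177	-0.001254	0.0015966	-0.0089063	8.537	116.92	0	0	8	0.000141
79	A	1	-0.00014948	-0.001057	0.0011149	-0.013103	8.769	127.09	0	0	8	0.000978
80	C	1	0.00052397	-0.002341	-0.0046498	0.012364	8.096	123.09	0	0	8	0.000116
81	R	1	-0.00016373	0.00047642	-0.00017503	0.018913	8.609	112.93	0	0	8	0.000138
82	V	1	0.00036573	-0.0022954	-0.0046831	-0.0092248	9.341	122.19	0	0	8	0.00382
83	N	1	-0.00045001	-0.0011916	0.0030153	0.016778	8.396	111	0	0	8	0.000137
84	H	0	-0.00039517	-0.001329	-0.0062164	-0.034285	7.678	129.04	0	0	8	NA
85	V	0	0.00022128	-0.0015276	-0.0011858	-0.01827	7.998	112.57	0	0	8	NA
86	T	1	-0.00010791	0.0014598	-0.0014169	-0.011259	8.478	113.63	0	0	8	NA
87	L	1	-0.00017183	-0.00020643	0.006797	-0.029579	8.482	109.85	0	0	8	NA
88	S	1	-0.00015984	-0.0010259	-0.0023485	0.031258	7.879	128.89	0	0	8	NA
89	Q	1	0.00042115	-0.0023293	0.0019105	0.0036858	9.166	112.37	0	0	8	NA
90	P	0	0.00050239	0.00076193	-0.0020292	0.030066	7.535	117.62	0	0	8	NA
91	K	0	0.00052793	-0.0012661	0.0046242	0.016004	7.922	114.03	0	0	8	NA
92	I	1	0.00033479	0.0016514	0.0075222	-0.0075353	8.703	121.25	0	0	8	NA
93	V	1	-4.4935e-05	2.7602e-05	-0.00057057	-0.0011682	8.975	117.8	0	0	8	NA
94	K	1	-0.00023398	0.0011501	0.0025286	0.039229	8.463	127.6	0	0	8	NA
95	W	1	-1.95e-05	0.00083548	0.00039819	0.026973	8.985	124.01	0	0	8	NA
96	D	1	-0.00034765	-0.0012242	0.00088873	0.011615	8.75	118.19	0	0	8	NA
97	R	1	0.00034833	6.7799e-05	-0.0010299	-0.026663	8.16	129.4	0	0	8	NA
98	D	0	0.00031249	-0.00039548	0.0008785	0.041749	7.583	111.64	0	0	8	NA
99	M	0	0.00035793	-0.00012128	0.0017055	0.011126	7.764	129.66	0	0	8	NA
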