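region_id	region	day1	day2
72	R Caudate_R (CAU)	0.054	0.010
73	L Putamen_L (PUT)	-0.375	0.065
74	R Putamen_R (PUT)	-0.449	0.010
63	L Supramarginal gyrus (SMG)	0.294	-0.008
58	R Postcentral gyrus (POST)	-0.379	-0.161
40	R Parahippocampus (PHIP)	0.092	0.015
15	L Inferior frontal gyrus, orbital (F3O)	0.142	0.214
86	R Middle temporal gyrus (T2)	-0.106	-0.153
83	L Temporal pole; superior temporal gyrus (T1P)	-0.128	-0.427
104	R Cerebellum 8	0.115	-0.028
3	L Superior frontal gyrus, dorsolateral (F1)	-0.117
4	R Superior frontal gyrus, dorsolateral (F1)	0.107
24	R Superior frontal gyrus, medial (F1M)	0.303
10	R Middle frontal gyrus, orbital (F2O)	-0.262
28	R Gyrus rectus (GR)	-0.081
9	L Middle frontal gyrus, orbital (F2O)	0.193
88	R Temporal pole; middle temporal gyrus (T2P)	0.000
64	R Supramarginal gyrus (SMG)	0.206
97	L Cerebellum 4 5	0.340
112	R Vermis 6	-0.374
99	L Cerebellum 6	-0.278
20	R Supplementary motor area (SMA)	-0.145
69	L Paracentral lobule (PCL)	-0.176
18	R Rolandic operculum (RO)	0.534
46	R Cuneus (Q)	0.566
48	R Lingual gyrus (LING)	-0.292
49	L Superior occipital lobe (O1)	0.290
52	R Middle occipital lobe (O2)	-0.262
56	R Fusiform gyrus (FUSI)	0.269
75	L Pallidum_L (PAL)		-0.172
76	R Pallidum_R (PAL)		-0.062
43	L Calcarine fissure and surrounding cortex (V1)		-0.134
44	R Calcarine fissure and surrounding cortex (V1)		0.122
51	L Middle occipital lobe (O2)		0.203
53	L Inferior occipital lobe (O3)		-0.209
82	R Superior temporal gyrus (T1)		0.252
12	R Inferior frontal gyrus, opercular (F3OP)		0.139
14	R Inferior frontal gyrus, triangular (F3T)		-0.148
6	R Superior frontal gyrus, orbital (F1O)		-0.039
26	R Superior frontal gyrus, medial orbital (F1MO)		-0.178
67	L Precuneus (PQ)		-0.172
68	R Precuneus (PQ)		0.107
85	L Middle temporal gyrus (T2)		0.091
17	L Rolandic operculum (RO)		0.542
57	L Postcentral gyrus (POST)		0.071
92	R Cerebellum crus 1		0.086
105	L Cerebellum 9		0.095
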