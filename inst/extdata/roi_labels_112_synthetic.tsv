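roi_index	hemisphere	label
0	L	Frontal pole
1	L	Insular cortex
2	L	Superior frontal gyrus
3	L	Middle frontal gyrus
4	L	Inferior frontal gyrus, pars triangularis
5	L	Inferior frontal gyrus, pars opercularis
6	L	Precentral gyrus
7	L	Temporal pole
8	L	Superior temporal gyrus, anterior division
9	L	Superior temporal gyrus, posterior division
10	L	Middle temporal gyrus, anterior division
11	L	Middle temporal gyrus, posterior division
12	L	Middle temporal gyrus, temporooccipital part
13	L	Inferior temporal gyrus, anterior division
14	L	Inferior temporal gyrus, posterior division
15	L	Inferior temporal gyrus, temporooccipital part
16	L	Postcentral gyrus
17	L	Superior parietal lobule
18	L	Supramarginal gyrus, anterior division
19	L	Supramarginal gyrus, posterior division
20	L	Angular gyrus
21	L	Lateral occipital cortex, superior division
22	L	Lateral occipital cortex, inferior division
23	L	Intracalcarine cortex
24	L	Frontal medial cortex
25	L	Juxtapositional lobule cortex
26	L	Subcallosal cortex
27	L	Paracingulate gyrus
28	L	Cingulate gyrus, anterior division
29	L	Cingulate gyrus, posterior division
30	L	Precuneous cortex
31	L	Cuneal cortex
32	L	Frontal orbital cortex
33	L	Parahippocampal gyrus, anterior division
34	L	Parahippocampal gyrus, posterior division
35	L	Lingual gyrus
36	L	Temporal fusiform cortex, anterior division
37	L	Temporal fusiform cortex, posterior division
38	L	Temporal occipital fusiform cortex
39	L	Occipital fusiform gyrus
40	L	Frontal operculum cortex
41	L	Central opercular cortex
42	L	Parietal operculum cortex
43	L	Planum polare
44	L	Heschl's gyrus
45	L	Planum temporale
46	L	Supracalcarine cortex
47	L	Occipital pole
48	L	Thalamus
49	L	Caudate
50	L	Putamen
51	L	Pallidum
52	L	Hippocampus
53	L	Amygdala
54	L	Accumbens
55	L	Brain-stem
56	R	Frontal pole
57	R	Insular cortex
58	R	Superior frontal gyrus
59	R	Middle frontal gyrus
60	R	Inferior frontal gyrus, pars triangularis
61	R	Inferior frontal gyrus, pars opercularis
62	R	Precentral gyrus
63	R	Temporal pole
64	R	Superior temporal gyrus, anterior division
65	R	Superior temporal gyrus, posterior division
66	R	Middle temporal gyrus, anterior division
67	R	Middle temporal gyrus, posterior division
68	R	Middle temporal gyrus, temporooccipital part
69	R	Inferior temporal gyrus, anterior division
70	R	Inferior temporal gyrus, posterior division
71	R	Inferior temporal gyrus, temporooccipital part
72	R	Postcentral gyrus
73	R	Superior parietal lobule
74	R	Supramarginal gyrus, anterior division
75	R	Supramarginal gyrus, posterior division
76	R	Angular gyrus
77	R	Lateral occipital cortex, superior division
78	R	Lateral occipital cortex, inferior division
79	R	Intracalcarine cortex
80	R	Frontal medial cortex
81	R	Juxtapositional lobule cortex
82	R	Subcallosal cortex
83	R	Paracingulate gyrus
84	R	Cingulate gyrus, anterior division
85	R	Cingulate gyrus, posterior division
86	R	Precuneous cortex
87	R	Cuneal cortex
88	R	Frontal orbital cortex
89	R	Parahippocampal gyrus, anterior division
90	R	Parahippocampal gyrus, posterior division
91	R	Lingual gyrus
92	R	Temporal fusiform cortex, anterior division
93	R	Temporal fusiform cortex, posterior division
94	R	Temporal occipital fusiform cortex
95	R	Occipital fusiform gyrus
96	R	Frontal operculum cortex
97	R	Central opercular cortex
98	R	Parietal operculum cortex
99	R	Planum polare
100	R	Heschl's gyrus
101	R	Planum temporale
102	R	Supracalcarine cortex
103	R	Occipital pole
104	R	Thalamus
105	R	Caudate
106	R	Putamen
107	R	Pallidum
108	R	Hippocampus
109	R	Amygdala
110	R	Accumbens
111	R	Brain-stem
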