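hemisphere	label	mni_x	mni_y	mni_z
L	Frontal pole	-25	53	8
L	Insular cortex	-36	1	0
R	Insular cortex	38	3	0
L	Inferior frontal gyrus, pars triangularis	-50	29	9
R	Inferior frontal gyrus, pars opercularis	52	15	16
L	Precentral gyrus	-34	-12	49
R	Temporal pole	41	13	-29
L	Superior temporal gyrus, anterior division	-56	-4	-8
R	Superior temporal gyrus, anterior division	57	-1	-10
L	Superior temporal gyrus, posterior division	-62	-29	4
L	Middle temporal gyrus, anterior division	-58	-4	-22
R	Middle temporal gyrus, posterior division	61	-22	-12
L	Inferior temporal gyrus, anterior division	-48	-5	-39
L	Inferior temporal gyrus, posterior division	-53	-28	-26
R	Inferior temporal gyrus, temporooccipital part	54	-50	-17
L	Postcentral gyrus	-39	-28	52
R	Postcentral gyrus	37	-27	53
L	Supramarginal gyrus, posterior division	-55	-46	34
R	Lateral occipital cortex, inferior division	45	-74	-2
L	Intracalcarine cortex	-10	-75	8
R	Intracalcarine cortex	12	-74	8
R	Frontal medial cortex	-5	44	-18
R	Juxtapositional lobule cortex (formerly supplementary motor cortex)	6	-3	58
R	Subcallosal cortex	6	20	-16
L	Frontal orbital cortex	-30	24	-16
R	Parahippocampal gyrus, anterior division	23	-8	-31
L	Lingual gyrus	-13	-66	-5
R	Lingual gyrus	14	-63	-5
R	Temporal fusiform cortex, posterior division	-36	-24	-28
L	Planum polare	-47	-5	-8
R	Planum polare	48	-4	-7
R	Heschl's gyrus (includes H1 and H2)	46	-17	7
L	Planum temporale	-53	-30	11
R	Planum temporale	55	-25	12
R	Supracalcarine cortex	9	-74	14
L	Hippocampus	-25	-23	-14
R	Amygdala	23	-4	-18
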