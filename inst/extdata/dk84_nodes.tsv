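index	name	hemisphere
0	L.Bankssts	L
1	L.CaudalAnteriorCingulate	L
2	L.CaudalMiddleFrontal	L
3	L.Cuneus	L
4	L.Entorhinal	L
5	L.Fusiform	L
6	L.InferiorParietal	L
7	L.InferiorTemporal	L
8	L.IsthmusCingulate	L
9	L.LateralOccipital	L
10	L.LateralOrbitoFrontal	L
11	L.Lingual	L
12	L.MedialOrbitoFrontal	L
13	L.MiddleTemporal	L
14	L.Parahippocampal	L
15	L.ParaCentral	L
16	L.ParsOpercularis	L
17	L.ParsOrbitalis	L
18	L.ParsTriangularis	L
19	L.Pericalcarine	L
20	L.PostCentral	L
21	L.PosteriorCingulate	L
22	L.PreCentral	L
23	L.Precuneus	L
24	L.RostralAnteriorCingulate	L
25	L.RostralMiddleFrontal	L
26	L.SuperiorFrontal	L
27	L.SuperiorParietal	L
28	L.SuperiorTemporal	L
29	L.Supramarginal	L
30	L.FrontalPole	L
31	L.TemporalPole	L
32	L.TransverseTemporal	L
33	L.Insula	L
34	L.CerebellumCortex	L
35	L.ThalamusProper	L
36	L.Caudate	L
37	L.Putamen	L
38	L.Pallidum	L
39	L.Hippocampus	L
40	L.Amygdala	L
41	L.AccumbensArea	L
42	R.Bankssts	R
43	R.CaudalAnteriorCingulate	R
44	R.CaudalMiddleFrontal	R
45	R.Cuneus	R
46	R.Entorhinal	R
47	R.Fusiform	R
48	R.InferiorParietal	R
49	R.InferiorTemporal	R
50	R.IsthmusCingulate	R
51	R.LateralOccipital	R
52	R.LateralOrbitoFrontal	R
53	R.Lingual	R
54	R.MedialOrbitoFrontal	R
55	R.MiddleTemporal	R
56	R.Parahippocampal	R
57	R.ParaCentral	R
58	R.ParsOpercularis	R
59	R.ParsOrbitalis	R
60	R.ParsTriangularis	R
61	R.Pericalcarine	R
62	R.PostCentral	R
63	R.PosteriorCingulate	R
64	R.PreCentral	R
65	R.Precuneus	R
66	R.RostralAnteriorCingulate	R
67	R.RostralMiddleFrontal	R
68	R.SuperiorFrontal	R
69	R.SuperiorParietal	R
70	R.SuperiorTemporal	R
71	R.Supramarginal	R
72	R.FrontalPole	R
73	R.TemporalPole	R
74	R.TransverseTemporal	R
75	R.Insula	R
76	R.CerebellumCortex	R
77	R.ThalamusProper	R
78	R.Caudate	R
79	R.Putamen	R
80	R.Pallidum	R
81	R.Hippocampus	R
82	R.Amygdala	R
83	R.AccumbensArea	R
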