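region_index	region_label
0	lh_G_and_S_frontomargin
1	lh_G_and_S_occipital_inf
2	lh_G_and_S_paracentral
3	lh_G_and_S_subcentral
4	lh_G_and_S_transv_frontopol
5	lh_G_and_S_cingul-Ant
6	lh_G_and_S_cingul-Mid-Ant
7	lh_G_and_S_cingul-Mid-Post
8	lh_G_cingul-Post-dorsal
9	lh_G_cingul-Post-ventral
10	lh_G_cuneus
11	lh_G_front_inf-Opercular
12	lh_G_front_inf-Orbital
13	lh_G_front_inf-Triangul
14	lh_G_front_middle
15	lh_G_front_sup
16	lh_G_Ins_lg_and_S_cent_ins
17	lh_G_insular_short
18	lh_G_occipital_middle
19	lh_G_occipital_sup
20	lh_G_oc-temp_lat-fusifor
21	lh_G_oc-temp_med-Lingual
22	lh_G_oc-temp_med-Parahip
23	lh_G_orbital
24	lh_G_pariet_inf-Angular
25	lh_G_pariet_inf-Supramar
26	lh_G_parietal_sup
27	lh_G_postcentral
28	lh_G_precentral
29	lh_G_precuneus
30	lh_G_rectus
31	lh_G_subcallosal
32	lh_G_temp_sup-G_T_transv
33	lh_G_temp_sup-Lateral
34	lh_G_temp_sup-Plan_polar
35	lh_G_temp_sup-Plan_tempo
36	lh_G_temporal_inf
37	lh_G_temporal_middle
38	lh_Lat_Fis-ant-Horizont
39	lh_Lat_Fis-ant-Vertical
40	lh_Lat_Fis-post
41	lh_Pole_occipital
42	lh_Pole_temporal
43	lh_S_calcarine
44	lh_S_central
45	lh_S_cingul-Marginalis
46	lh_S_circular_insula_ant
47	lh_S_circular_insula_inf
48	lh_S_circular_insula_sup
49	lh_S_collat_transv_ant
50	lh_S_collat_transv_post
51	lh_S_front_inf
52	lh_S_front_middle
53	lh_S_front_sup
54	lh_S_interm_prim-Jensen
55	lh_S_intrapariet_and_P_trans
56	lh_S_oc_middle_and_Lunatus
57	lh_S_oc_sup_and_transversal
58	lh_S_occipital_ant
59	lh_S_oc-temp_lat
60	lh_S_oc-temp_med_and_Lingual
61	lh_S_orbital_lateral
62	lh_S_orbital_med-olfact
63	lh_S_orbital-H_Shaped
64	lh_S_parieto_occipital
65	lh_S_pericallosal
66	lh_S_postcentral
67	lh_S_precentral-inf-part
68	lh_S_precentral-sup-part
69	lh_S_suborbital
70	lh_S_subparietal
71	lh_S_temporal_inf
72	lh_S_temporal_sup
73	lh_S_temporal_transverse
74	rh_G_and_S_frontomargin
75	rh_G_and_S_occipital_inf
76	rh_G_and_S_paracentral
77	rh_G_and_S_subcentral
78	rh_G_and_S_transv_frontopol
79	rh_G_and_S_cingul-Ant
80	rh_G_and_S_cingul-Mid-Ant
81	rh_G_and_S_cingul-Mid-Post
82	rh_G_cingul-Post-dorsal
83	rh_G_cingul-Post-ventral
84	rh_G_cuneus
85	rh_G_front_inf-Opercular
86	rh_G_front_inf-Orbital
87	rh_G_front_inf-Triangul
88	rh_G_front_middle
89	rh_G_front_sup
90	rh_G_Ins_lg_and_S_cent_ins
91	rh_G_insular_short
92	rh_G_occipital_middle
93	rh_G_occipital_sup
94	rh_G_oc-temp_lat-fusifor
95	rh_G_oc-temp_med-Lingual
96	rh_G_oc-temp_med-Parahip
97	rh_G_orbital
98	rh_G_pariet_inf-Angular
99	rh_G_pariet_inf-Supramar
100	rh_G_parietal_sup
101	rh_G_postcentral
102	rh_G_precentral
103	rh_G_precuneus
104	rh_G_rectus
105	rh_G_subcallosal
106	rh_G_temp_sup-G_T_transv
107	rh_G_temp_sup-Lateral
108	rh_G_temp_sup-Plan_polar
109	rh_G_temp_sup-Plan_tempo
110	rh_G_temporal_inf
111	rh_G_temporal_middle
112	rh_Lat_Fis-ant-Horizont
113	rh_Lat_Fis-ant-Vertical
114	rh_Lat_Fis-post
115	rh_Pole_occipital
116	rh_Pole_temporal
117	rh_S_calcarine
118	rh_S_central
119	rh_S_cingul-Marginalis
120	rh_S_circular_insula_ant
121	rh_S_circular_insula_inf
122	rh_S_circular_insula_sup
123	rh_S_collat_transv_ant
124	rh_S_collat_transv_post
125	rh_S_front_inf
126	rh_S_front_middle
127	rh_S_front_sup
128	rh_S_interm_prim-Jensen
129	rh_S_intrapariet_and_P_trans
130	rh_S_oc_middle_and_Lunatus
131	rh_S_oc_sup_and_transversal
132	rh_S_occipital_ant
133	rh_S_oc-temp_lat
134	rh_S_oc-temp_med_and_Lingual
135	rh_S_orbital_lateral
136	rh_S_orbital_med-olfact
137	rh_S_orbital-H_Shaped
138	rh_S_parieto_occipital
139	rh_S_pericallosal
140	rh_S_postcentral
141	rh_S_precentral-inf-part
142	rh_S_precentral-sup-part
143	rh_S_suborbital
144	rh_S_subparietal
145	rh_S_temporal_inf
146	rh_S_temporal_sup
147	rh_S_temporal_transverse
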