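index	name	system
1	Precentral_L	cortical
2	Precentral_R	cortical
3	Frontal_Sup_L	cortical
4	Frontal_Sup_R	cortical
5	Frontal_Sup_Orb_L	cortical
6	Frontal_Sup_Orb_R	cortical
7	Frontal_Mid_L	cortical
8	Frontal_Mid_R	cortical
9	Frontal_Inf_Oper_L	cortical
10	Frontal_Inf_Oper_R	cortical
11	Frontal_Inf_Tri_L	cortical
12	Frontal_Inf_Tri_R	cortical
13	Frontal_Inf_Orb_L	cortical
14	Frontal_Inf_Orb_R	cortical
15	Rolandic_Oper_L	cortical
16	Rolandic_Oper_R	cortical
17	Supp_Motor_Area_L	cortical
18	Supp_Motor_Area_R	cortical
19	Frontal_Sup_Medial_L	cortical
20	Frontal_Sup_Medial_R	cortical
21	Frontal_Med_Orb_L	cortical
22	Frontal_Med_Orb_R	cortical
23	Rectus_L	cortical
24	Rectus_R	cortical
25	Insula_L	cortical
26	Insula_R	cortical
27	Cingulum_Ant_L	cortical
28	Cingulum_Ant_R	cortical
29	Cingulum_Mid_L	cortical
30	Cingulum_Mid_R	cortical
31	Cingulum_Post_L	cortical
32	Cingulum_Post_R	cortical
33	Hippocampus_L	cortical
34	Hippocampus_R	cortical
35	ParaHippocampal_L	cortical
36	ParaHippocampal_R	cortical
37	Amygdala_L	cortical
38	Amygdala_R	cortical
39	Calcarine_L	cortical
40	Calcarine_R	cortical
41	Cuneus_L	cortical
42	Cuneus_R	cortical
43	Lingual_L	cortical
44	Lingual_R	cortical
45	Occipital_Sup_L	cortical
46	Occipital_Sup_R	cortical
47	Occipital_Mid_L	cortical
48	Occipital_Mid_R	cortical
49	Occipital_Inf_L	cortical
50	Occipital_Inf_R	cortical
51	Fusiform_L	cortical
52	Fusiform_R	cortical
53	Postcentral_L	cortical
54	Postcentral_R	cortical
55	Parietal_Sup_L	cortical
56	Parietal_Sup_R	cortical
57	Parietal_Inf_L	cortical
58	Parietal_Inf_R	cortical
59	SupraMarginal_L	cortical
60	SupraMarginal_R	cortical
61	Angular_L	cortical
62	Angular_R	cortical
63	Precuneus_L	cortical
64	Precuneus_R	cortical
65	Paracentral_Lobule_L	cortical
66	Paracentral_Lobule_R	cortical
67	Temporal_Sup_L	cortical
68	Temporal_Sup_R	cortical
69	Temporal_Pole_Sup_L	cortical
70	Temporal_Pole_Sup_R	cortical
71	Temporal_Mid_L	cortical
72	Temporal_Mid_R	cortical
73	Temporal_Inf_L	cortical
74	Temporal_Inf_R	cortical
75	Cerebelum_Crus1_L	cortical
76	Cerebelum_Crus1_R	cortical
77	Cerebelum_VI_L	cortical
78	Cerebelum_VI_R	cortical
79	Vermis_VI	cortical
80	Vermis_VIII	cortical
81	Caudate_L	subcortical
82	Caudate_R	subcortical
83	Putamen_L	subcortical
84	Putamen_R	subcortical
85	Pallidum_Ext_L	subcortical
86	Pallidum_Ext_R	subcortical
87	Pallidum_Int_L	subcortical
88	Pallidum_Int_R	subcortical
89	Thalamus_L	subcortical
90	Thalamus_R	subcortical
91	Subthalamic_Nucleus_L	subcortical
92	Subthalamic_Nucleus_R	subcortical
93	Substantia_Nigra_L	subcortical
94	Substantia_Nigra_R	subcortical
95	Red_Nucleus_L	subcortical
96	Red_Nucleus_R	subcortical
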