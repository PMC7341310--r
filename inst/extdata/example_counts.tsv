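gene_id	muscle_hyb_1	muscle_hyb_2	muscle_hyb_3	muscle_pat_1	muscle_pat_2	muscle_pat_3	muscle_mat_1	muscle_mat_2	muscle_mat_3
g00001	177	189	242	81	137	51	558	264	721
g00002	111	82	118	45	154	62	68	78	51
g00003	144	61	163	130	67	140	129	80	137
g00004	109	78	139	131	136	146	175	93	286
g00005	523	291	290	218	431	275	297	209	270
g00006	45	30	38	434	790	522	232	107	172
g00007	262	267	168	221	508	241	299	206	216
g00008	706	462	317	334	278	286	719	760	610
g00009	54	67	30	34	65	24	80	26	57
g00010	738	998	1216	406	1102	677	235	229	238
g00011	199	180	163	183	143	184	253	137	176
g00012	452	265	231	347	245	142	377	170	218
g00013	36	36	27	140	157	81	566	291	295
g00014	79	75	54	39	89	62	59	64	92
g00015	269	286	217	53	64	60	372	191	131
g00016	77	72	109	51	60	67	83	51	83
g00017	109	141	86	130	190	171	451	292	532
g00018	163	225	107	151	280	104	286	163	60
g00019	242	149	125	320	173	213	87	45	55
g00020	102	110	155	55	141	130	187	44	115
g00021	50	37	49	165	223	90	62	52	23
g00022	262	141	383	169	239	285	305	422	244
g00023	75	77	86	113	99	99	35	21	33
g00024	156	136	141	59	76	28	548	177	191
g00025	276	235	484	218	317	411	100	64	161
g00026	511	275	521	375	274	471	296	231	569
g00027	48	77	77	108	267	197	51	26	63
g00028	130	199	266	153	254	241	74	50	71
g00029	88	50	76	79	84	90	50	17	54
g00030	130	79	146	115	79	182	171	104	141
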