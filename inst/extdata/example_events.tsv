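event_id	gene_id	event_type	chrom	strand	inclusion_chain	exclusion_chain	len_inclusion	len_exclusion	I:muscle_hyb_1	S:muscle_hyb_1	I:muscle_hyb_2	S:muscle_hyb_2	I:muscle_hyb_3	S:muscle_hyb_3	I:muscle_pat_1	S:muscle_pat_1	I:muscle_pat_2	S:muscle_pat_2	I:muscle_pat_3	S:muscle_pat_3	I:muscle_mat_1	S:muscle_mat_1	I:muscle_mat_2	S:muscle_mat_2	I:muscle_mat_3	S:muscle_mat_3
ev00001	sg00001	SE	chrSim	+	1000-1200,1500-1600,1900-2100	1000-1200,1900-2100	100	50	39	44	26	35	37	37	30	40	31	33	31	50	8	72	7	73	6	65
ev00002	sg00002	RI	chrSim	-	11000-11700	11000-11200,11500-11700	100	50	39	29	57	48	38	35	53	44	40	28	50	35	48	36	41	32	36	33
ev00003	sg00003	A5SS	chrSim	+	21000-21300,21600-21800	21000-21200,21600-21800	50	50	20	68	13	70	7	67	35	48	30	41	35	43	38	52	30	47	42	34
ev00004	sg00004	SE	chrSim	-	31000-31200,31500-31600,31900-32100	31000-31200,31900-32100	100	50	74	8	57	8	56	14	52	37	54	33	49	23	61	27	43	27	48	30
ev00005	sg00004	RI	chrSim	+	41000-41700	41000-41200,41500-41700	100	50	34	37	41	50	40	45	46	42	40	49	34	40	54	43	36	57	41	33
ev00006	sg00005	A5SS	chrSim	-	51000-51300,51600-51800	51000-51200,51600-51800	50	50	69	24	55	28	55	24	32	49	34	43	34	58	37	44	34	43	31	38
ev00007	sg00006	SE	chrSim	+	61000-61200,61500-61600,61900-62100	61000-61200,61900-62100	100	50	57	20	66	21	66	22	42	26	56	19	71	21	75	17	65	17	57	18
ev00008	sg00007	RI	chrSim	-	71000-71700	71000-71200,71500-71700	100	50	40	35	31	42	42	43	22	67	23	54	33	49	50	30	60	22	58	30
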