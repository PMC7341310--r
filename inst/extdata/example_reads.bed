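chrSim	1000	2100	lr_ev00001_001	0	+	1000	2100	0,0,0	3	200,100,200,	0,500,900,
chrSim	1000	2100	lr_ev00001_002	0	+	1000	2100	0,0,0	3	200,100,200,	0,500,900,
chrSim	1000	2100	lr_ev00001_003	0	+	1000	2100	0,0,0	2	200,200,	0,900,
chrSim	1000	2100	lr_ev00001_004	0	+	1000	2100	0,0,0	2	200,200,	0,900,
chrSim	1000	2100	lr_ev00001_005	0	+	1000	2100	0,0,0	2	200,200,	0,900,
chrSim	1000	2100	lr_ev00001_006	0	+	1000	2100	0,0,0	2	200,200,	0,900,
chrSim	1000	2100	lr_ev00001_007	0	+	1000	2100	0,0,0	2	200,200,	0,900,
chrSim	21000	21800	lr_ev00003_001	0	+	21000	21800	0,0,0	2	300,200,	0,600,
chrSim	21000	21800	lr_ev00003_002	0	+	21000	21800	0,0,0	2	300,200,	0,600,
chrSim	21000	21800	lr_ev00003_003	0	+	21000	21800	0,0,0	2	200,200,	0,600,
chrSim	31000	32100	lr_ev00004_001	0	-	31000	32100	0,0,0	3	200,100,200,	0,500,900,
chrSim	41000	41700	lr_ev00005_001	0	+	41000	41700	0,0,0	1	700,	0,
chrSim	41000	41700	lr_ev00005_002	0	+	41000	41700	0,0,0	1	700,	0,
chrSim	41000	41700	lr_ev00005_003	0	+	41000	41700	0,0,0	1	700,	0,
chrSim	41000	41700	lr_ev00005_004	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	41000	41700	lr_ev00005_005	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	41000	41700	lr_ev00005_006	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	41000	41700	lr_ev00005_007	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	41000	41700	lr_ev00005_008	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	41000	41700	lr_ev00005_009	0	+	41000	41700	0,0,0	2	200,200,	0,500,
chrSim	51000	51800	lr_ev00006_001	0	-	51000	51800	0,0,0	2	300,200,	0,600,
chrSim	51000	51800	lr_ev00006_002	0	-	51000	51800	0,0,0	2	300,200,	0,600,
chrSim	51000	51800	lr_ev00006_003	0	-	51000	51800	0,0,0	2	200,200,	0,600,
chrSim	51000	51800	lr_ev00006_004	0	-	51000	51800	0,0,0	2	200,200,	0,600,
chrSim	51000	51800	lr_ev00006_005	0	-	51000	51800	0,0,0	2	200,200,	0,600,
chrSim	61000	62100	lr_ev00007_001	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	61000	62100	lr_ev00007_002	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	61000	62100	lr_ev00007_003	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	61000	62100	lr_ev00007_004	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	61000	62100	lr_ev00007_005	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	61000	62100	lr_ev00007_006	0	+	61000	62100	0,0,0	3	200,100,200,	0,500,900,
chrSim	71000	71700	lr_ev00008_001	0	-	71000	71700	0,0,0	1	700,	0,
chrSim	71000	71700	lr_ev00008_002	0	-	71000	71700	0,0,0	2	200,200,	0,500,
chrSim	71000	71700	lr_ev00008_003	0	-	71000	71700	0,0,0	2	200,200,	0,500,
chrSim	71000	71700	lr_ev00008_004	0	-	71000	71700	0,0,0	2	200,200,	0,500,
chrSim	71000	71700	lr_ev00008_005	0	-	71000	71700	0,0,0	2	200,200,	0,500,
chrSim	71000	71700	lr_ev00008_006	0	-	71000	71700	0,0,0	2	200,200,	0,500,
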