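gene	previously_reported	shm_indicator	total_snvs	mutated_samples	titv_ratio	titv_p	motif_enrichment	motif_p	cg_at_enrichment	cg_at_p	rpkm_fold_change	avg_rpkm_tumor	avg_rpkm_normal_bcell
BCL6	1	0.1389	179	27	1.27	0.06	1.41	0.0919	0.77	0.5	0.55739	61.46	160.93086
BCL2	1	0.2642	146	11	0.8	0.5	1.47	0.0738	0.79	0.5	1.29298	20.73	2.59639
BTG2	0	0.0123	55	18	1.04	0.45	2.78	0.0002	1.05	0.0172	-0.27272	149.68	223.5928
TMSB4X	0	0.0201	52	17	0.79	0.5	1.69	0.1114	1.41	0.0001	0.11158	1485.88	1017.2736
ZFP36L1	0	0.0000	52	16	1.17	0.29	4.18	0	1.26	0.0009	0.05879	50.49	142.76265
RHOH	1	0.0509	42	17	0.68	0.5	2.91	0.0005	0.81	0.5	0.01346	76.73	352.06877
SERPINA9	0	0.1296	36	7	0.57	0.5	2.15	0.0345	1.03	0.1261	5.48905	277.47	237.10067
CD83	0	0.0006	34	8	1.13	0.37	3.49	0.0001	1.67	0	1.08042	162.19	478.47502
SGK1	0	0.0000	34	5	0.62	0.5	5.5	0	1.37	0.0103	0.1586	2.9	4.48411
BCL7A	1	0.0083	32	14	1.46	0.14	4.29	0	0.9	0.5	0.73039	31.17	96.05465
BACH2	0	0.5000	30	8	0.25	0.5	0.67	0.5	0.75	0.5	0.30362	8.07	52.5643
LTB	0	0.0794	23	10	1.3	0.27	2.72	0.0156	1.15	0.1208	1.81466	142.64	189.28412
BIRC3	0	0.1158	21	12	1.1	0.41	2.03	0.0975	1.4	0.0385	-0.10012	80.95	175.95683
HIST1H2AC	0	0.0009	19	9	1.71	0.13	4.95	0	1.47	0.0123	0	0.2	0.08058
TCL1A	0	0.2012	17	8	0.55	0.5	1.03	0.4869	1.48	0.0335	-0.07685	248.73	709.73845
ST6GAL1	1	0.2318	15	8	0.88	0.5	2.17	0.1233	1.03	0.202	0.23782	64.48	149.40245
CD74	0	0.0032	14	8	0.56	0.5	5.18	0	1.7	0.0061	0.44198	10559.9	8227.8865
SOCS1	1	0.0272	14	5	1.33	0.3	3.3	0.0117	1.38	0.0058	0.16955	26.18	39.5316
IRF8	0	0.2448	13	9	1.6	0.2	1.19	0.4275	1.14	0.1694	-0.0691	174.1	462.84745
BTG1	0	0.0683	13	9	1.17	0.39	3.55	0.0076	1.22	0.1065	0.12187	191.66	975.71198
CR607557	0	0.0008	13	9	1.6	0.2	6.69	0	1.11	0.2004	0	0	0
LRMP	1	0.2823	13	7	0.63	0.5	1.08	0.4667	1.48	0.0965	0.22716	149.99	276.99144
IRF4	1	0.0208	13	4	5.5	0.01	2.63	0.0714	1.28	0.0201	1.82701	106.08	29.07161
CIITA	1	0.0003	12	9	1	0.5	6.29	0	1.78	0.001	0.49221	25.66	23.75111
DTX1	0	0.0294	12	8	3	0.04	3.71	0.0059	1.26	0.1041	0.42032	87.73	151.20776
CXCR4	0	0.0025	12	7	0.71	0.5	5.9	0	1.68	0.002	0.42432	143.96	968.41417
PIM1	1	0.0146	12	7	1	0.5	4.6	0.0003	1.47	0.0255	0.96916	84.02	165.35743
S1PR2	0	0.0183	11	7	1.75	0.18	5.25	0.0005	1.19	0.0689	0.59678	22.33	96.04705
MALAT1	0	0.1786	11	7	1.2	0.38	2.6	0.0729	1.21	0.2048	0	0	0
SPRED2	0	0.2356	11	6	0.57	0.5	2.89	0.0523	0.75	0.5	1.46507	12.24	22.09212
PAX5	1	0.0114	10	7	1.5	0.26	6.39	0.0001	1.39	0.0726	-0.2793	52.52	127.01243
DMD	0	0.0239	10	3	2.33	0.1	3.36	0.0301	2.28	0.0044	1.50279	10.53	3.6875
LLT1	0	0.2591	10	3	2.33	0.1	1.49	0.338	0.49	0.5	-0.21925	47.98	86.73398
ETS1	0	0.1877	9	8	0.5	0.5	2.08	0.2211	1.61	0.0598	0.40109	58.37	102.81003
DUSP2	0	0.0040	9	4	2	0.16	6.18	0	1.18	0.0532	0.65633	119.76	160.9238
AK123543	0	0.0609	8	5	0	0.5	4.1	0.0127	1.71	0.0355	0	0	0
POU2AF1	0	0.5000	7	6	0.75	0.5	0	0.5	0.61	0.5	-0.12034	153.93	429.77219
GADD45B	0	0.1136	7	6	6	0.03	2.58	0.1562	0.93	0.3192	-0.04866	30.99	132.9862
MS4A1	0	0.1944	7	4	6	0.03	0	0.5	0.66	0.5	0.03938	644.07	715.41695
P2RY8	0	0.3182	7	3	1.33	0.35	2.34	0.1826	0.92	0.5	0	0.49	1.30263
GRHPR	0	0.1429	6	5	2	0.21	0	0.5	1.81	0.0282	-0.17425	57.62	27.42158
NCOA3	0	0.1770	6	4	5	0.05	0	0.5	1.39	0.2165	0.22822	42.81	76.49762
UBE2J1	0	0.0140	6	3	6	0.01	5.29	0.0032	1.57	0.1199	-0.31589	67.82	239.48779
MYC	1	0.0630	6	3	1	0.5	5.38	0.0029	1.42	0.1713	0.63538	22.53	27.42303
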