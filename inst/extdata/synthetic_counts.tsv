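taxon	sample_001	sample_002	sample_003	sample_004	sample_005	sample_006	sample_007	sample_008	sample_009	sample_010	sample_011	sample_012	sample_013	sample_014	sample_015	sample_016	sample_017	sample_018	sample_019	sample_020	sample_021	sample_022	sample_023	sample_024	sample_025	sample_026	sample_027	sample_028	sample_029	sample_030
taxon_001	10	4	3	0	0	0	0	4	3	4	0	9	5	1	14	1	1	0	2	1	16	0	2	9	8	2	3	1	2	3
taxon_002	100	0	16	0	9	13	33	35	27	18	3	0	47	11	0	82	30	5	11	0	9	40	7	51	36	60	53	22	0	5
taxon_003	13	584	66	5	242	85	7054	612	3097	432	215	1115	30	1667	1038	0	6892	0	165	1228	1377	109	699	337	792	261	3112	159	2	723
taxon_004	3	54	271	13	64	11	88	1	4	4	52	18	3	12	27	0	70	38	18	8	226	14	51	11	4	47	259	13	8	0
taxon_005	19	8	4	31	0	0	0	1	0	3	1	1	9	24	0	1	0	78	0	6	1	9	3	5	0	3	5	0	0	3
taxon_006	33	64	22	52	1	0	11	323	2	10	51	1	0	61	6	0	51	1	121	40	170	0	22	7	0	69	103	11	21	35
taxon_007	17	93	283	261	615	1059	24	211	226	146	4	74	7	9	6	194	318	1	0	282	821	1014	3	922	563	366	1320	271	428	67
taxon_008	22	0	1	10	3	0	6	5	0	10	3	9	3	1	56	16	1	3	0	0	4	1	5	35	2	7	2	7	0	4
taxon_009	1	31	512	10	32	276	53	27	24	49	276	31	1	0	50	6	7	75	136	5	0	0	90	93	66	21	7	141	2	2
taxon_010	0	125	41	18	39	1	82	108	7	0	88	38	8	245	41	46	4	42	9	38	55	26	4	160	328	154	161	70	0	39
taxon_011	0	4	26	24	15	11	7	0	114	43	26	14	16	60	1	2	14	20	1	48	1	58	2	22	14	1	2	86	0	5
taxon_012	187	211	169	484	675	283	498	311	3	26	14	106	3	17	390	36	318	1215	148	122	0	89	1441	182	20	0	652	446	48	15
taxon_013	413	203	144	11	1965	39	179	46	516	62	11	142	14	254	53	23	171	127	0	23	309	210	84	490	123	13	17	153	108	62
taxon_014	91	54	3	61	19	54	9	62	57	1	29	0	14	1	80	0	0	35	5	1	70	8	1	48	26	0	36	15	21	16
taxon_015	118	224	6	1	24	11	13	2	8	66	45	37	85	1	298	0	0	137	62	41	88	42	2	83	66	17	57	0	0	3
taxon_016	11	1	2	0	22	8	3	0	5	6	0	0	0	10	1	0	11	4	1	0	4	2	0	0	1	2	0	0	1	5
taxon_017	0	38	3	0	2	25	23	29	18	110	181	38	66	3	5	24	31	48	0	58	54	4	1	205	65	201	2	19	35	3
taxon_018	343	1846	2667	4652	34	1146	45	1027	997	12244	1131	3	23	6	161	1495	158	7	4598	107	113	2348	70	186	165	13	465	0	4743	1029
taxon_019	0	20	2	39	28	17	25	3	110	93	27	24	0	10	11	8	6	1	2	63	0	17	2	16	2	17	3	4	1	2
taxon_020	20	35	0	3	5	0	27	155	3	176	58	8	18	7	1	0	37	0	13	114	5	0	3	15	20	45	6	29	4	1
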