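sample	fgfr1_total	cen8_total	n_cluster	n_nuclei
SAMPLE_001	92	127	0	50
SAMPLE_002	96	117	0	50
SAMPLE_003	302	105	25	50
SAMPLE_004	86	115	0	50
SAMPLE_005	81	115	0	50
SAMPLE_006	94	118	0	50
SAMPLE_007	98	123	0	50
SAMPLE_008	107	126	0	50
SAMPLE_009	88	119	0	50
SAMPLE_010	98	121	0	50
SAMPLE_011	88	136	0	50
SAMPLE_012	112	108	0	50
SAMPLE_013	106	122	0	50
SAMPLE_014	74	116	0	50
SAMPLE_015	85	115	0	50
SAMPLE_016	105	118	0	50
SAMPLE_017	111	137	0	50
SAMPLE_018	238	113	4	50
SAMPLE_019	94	99	0	50
SAMPLE_020	382	122	30	50
SAMPLE_021	120	120	0	50
SAMPLE_022	102	106	0	50
SAMPLE_023	93	126	0	50
SAMPLE_024	322	116	31	50
SAMPLE_025	249	121	10	50
SAMPLE_026	413	109	24	50
SAMPLE_027	93	107	0	50
SAMPLE_028	106	117	0	50
SAMPLE_029	91	122	0	50
SAMPLE_030	96	123	0	50
SAMPLE_031	90	113	0	50
SAMPLE_032	111	118	0	50
SAMPLE_033	79	98	0	50
SAMPLE_034	90	109	0	50
SAMPLE_035	85	114	0	50
SAMPLE_036	77	112	0	50
SAMPLE_037	472	117	32	50
SAMPLE_038	117	115	0	50
SAMPLE_039	95	125	0	50
SAMPLE_040	99	113	0	50
SAMPLE_041	104	128	0	50
SAMPLE_042	100	122	0	50
SAMPLE_043	93	117	0	50
SAMPLE_044	102	116	0	50
SAMPLE_045	108	118	0	50
SAMPLE_046	96	118	0	50
SAMPLE_047	274	112	10	50
SAMPLE_048	105	113	0	50
SAMPLE_049	405	120	26	50
SAMPLE_050	94	115	0	50
SAMPLE_051	86	100	0	50
SAMPLE_052	90	131	0	50
SAMPLE_053	102	106	0	50
SAMPLE_054	96	118	0	50
SAMPLE_055	97	119	0	50
SAMPLE_056	103	131	0	50
SAMPLE_057	85	118	0	50
SAMPLE_058	95	125	0	50
SAMPLE_059	111	113	0	50
SAMPLE_060	105	122	0	50
SAMPLE_061	113	112	0	50
SAMPLE_062	100	111	0	50
SAMPLE_063	100	121	0	50
SAMPLE_064	87	108	0	50
SAMPLE_065	399	110	33	50
SAMPLE_066	96	118	0	50
SAMPLE_067	114	124	0	50
SAMPLE_068	96	115	0	50
SAMPLE_069	99	109	0	50
SAMPLE_070	121	116	0	50
SAMPLE_071	321	119	21	50
SAMPLE_072	99	103	0	50
SAMPLE_073	93	115	0	50
SAMPLE_074	429	99	30	50
SAMPLE_075	104	112	0	50
SAMPLE_076	99	98	0	50
SAMPLE_077	87	91	0	50
SAMPLE_078	86	116	0	50
SAMPLE_079	91	111	0	50
SAMPLE_080	103	115	0	50
SAMPLE_081	84	101	0	50
SAMPLE_082	88	122	0	50
SAMPLE_083	92	101	0	50
SAMPLE_084	90	121	0	50
SAMPLE_085	101	114	0	50
SAMPLE_086	108	136	0	50
SAMPLE_087	103	117	0	50
SAMPLE_088	95	126	0	50
SAMPLE_089	87	123	0	50
SAMPLE_090	436	129	29	50
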