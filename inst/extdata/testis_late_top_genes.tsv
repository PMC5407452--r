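rank	gene	log2fc	fold_change
1	CYP17A1	5.27	38.5
2	LHCGR	3.47	11.1
3	INSL3	3.13	8.8
4	CYP11A1	3.08	8.5
5	CALB2	2.86	7.3
6	SCARB1	2.83	7.1
7	STAR	2.54	5.8
8	DHCR24	2.22	4.6
9	ABCA10	2.21	4.6
10	MGARP	2.16	4.5
11	MSMO1	2.12	4.3
12	RNU6-1160P	2.11	4.3
13	GRAMD1B	2.04	4.1
14	HSD17B6	2.03	4.1
15	EGFLAM	2.02	4.1
16	ABCA8	2.02	4.0
17	IDI1	2.01	4.0
18	LDLR	1.95	3.9
19	LUM	1.95	3.9
20	SPARCL1	1.94	3.8
22	HSD3B2	1.92	3.8
23	DHCR7	1.92	3.8
24	C7	1.87	3.7
25	HSD17B3	1.87	3.7
28	HPGD	1.84	3.6
29	PAPSS2	1.83	3.5
41	FDPS	1.61	3.0
42	MVD	1.59	3.0
49	NPC1	1.55	2.9
68	INHA	1.40	2.6
100	AMH	1.18	2.3
119	POR	1.07	2.1
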