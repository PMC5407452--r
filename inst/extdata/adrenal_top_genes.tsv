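rank	gene	log2fc	fold_change
1	CYP17A1	7.91	240.2
2	CYP11A1	6.85	115.4
3	SULT2A1	6.60	97.3
4	STAR	6.20	73.4
5	MC2R	5.96	62.3
6	CYP11B1	5.58	47.8
7	MGARP	5.21	37.1
8	GSTA1	5.15	35.5
9	MAP3K15	5.11	34.5
10	NPR3	4.62	24.6
11	ASB4	4.60	24.3
12	HPGD	4.46	22.0
13	GNRHR	4.43	21.6
14	C7	4.34	20.3
15	SERPINA5	4.26	19.2
16	FDX1P1	4.26	19.1
17	SCARB1	4.15	17.8
18	NRK	4.09	17.1
19	CYP21A2	4.09	17.1
20	FDX1	4.03	16.3
21	PAPSS2	4.00	16.0
22	DHCR24	4.00	15.9
25	TDGF1	3.96	15.6
36	INHA	3.67	12.8
43	APOA1	3.42	10.7
46	SAMD9	3.34	10.2
49	NR0B1	3.25	9.5
50	HSD3B2	3.19	9.1
60	NR5A1	2.96	7.8
72	LDLR	2.81	7.0
77	AMHR2	2.73	6.7
105	POR	2.53	5.8
117	MRAP	2.43	5.4
142	NPC1	2.31	5.0
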