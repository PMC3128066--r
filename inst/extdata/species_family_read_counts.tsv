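species	family	reads	pct
C_simus	BPP	178	13.4
B_asper_Car	BPP	4232	15
B_asper_Pac	BPP	169	12.2
C_godmani	BPP	818	8.3
A_picadoi	BPP	1634	16.4
A_mexicanus	BPP	406	13
B_schlegelii	BPP	444	15.3
B_lateralis	BPP	1350	23.6
C_simus	CRISP	0	0
B_asper_Car	CRISP	245	0.8
B_asper_Pac	CRISP	3	0.2
C_godmani	CRISP	253	2.6
A_picadoi	CRISP	261	2.6
A_mexicanus	CRISP	17	0.5
B_schlegelii	CRISP	105	3.6
B_lateralis	CRISP	182	3.2
C_simus	CTL	32	2.4
B_asper_Car	CTL	287	1
B_asper_Pac	CTL	19	1.3
C_godmani	CTL	23	0.2
A_picadoi	CTL	476	4.8
A_mexicanus	CTL	15	0.5
B_schlegelii	CTL	7	0.2
B_lateralis	CTL	180	3.1
C_simus	GF	60	4.5
B_asper_Car	GF	275	0.9
B_asper_Pac	GF	38	2.7
C_godmani	GF	64	0.6
A_picadoi	GF	56	0.6
A_mexicanus	GF	50	1.6
B_schlegelii	GF	142	4.9
B_lateralis	GF	103	1.8
C_simus	LAO	50	3.8
B_asper_Car	LAO	1197	4.2
B_asper_Pac	LAO	33	2.4
C_godmani	LAO	537	5.5
A_picadoi	LAO	308	3.1
A_mexicanus	LAO	121	3.9
B_schlegelii	LAO	92	3.2
B_lateralis	LAO	197	3.4
C_simus	PLA2	161	12.1
B_asper_Car	PLA2	5026	17.8
B_asper_Pac	PLA2	195	14.2
C_godmani	PLA2	777	7.9
A_picadoi	PLA2	228	2.3
A_mexicanus	PLA2	224	7.2
B_schlegelii	PLA2	278	9.6
B_lateralis	PLA2	176	3
C_simus	SVMP	86	6.5
B_asper_Car	SVMP	11733	41.6
B_asper_Pac	SVMP	559	40.6
C_godmani	SVMP	4144	42.2
A_picadoi	SVMP	5583	56.1
A_mexicanus	SVMP	1204	38.7
B_schlegelii	SVMP	762	26.3
B_lateralis	SVMP	2575	44.9
C_simus	SP	373	28.1
B_asper_Car	SP	3790	13.4
B_asper_Pac	SP	114	8.3
C_godmani	SP	2770	28.1
A_picadoi	SP	1089	10.9
A_mexicanus	SP	692	22.2
B_schlegelii	SP	594	20.5
B_lateralis	SP	597	10.4
C_simus	5NTase	3	0.2
B_asper_Car	5NTase	214	0.7
B_asper_Pac	5NTase	3	0.2
C_godmani	5NTase	67	0.7
A_picadoi	5NTase	13	0.1
A_mexicanus	5NTase	27	0.8
B_schlegelii	5NTase	5	0.17
B_lateralis	5NTase	42	0.7
C_simus	PDE	3	0.2
B_asper_Car	PDE	56	0.2
B_asper_Pac	PDE	3	0.2
C_godmani	PDE	13	0.1
A_picadoi	PDE	8	0.08
A_mexicanus	PDE	0	0
B_schlegelii	PDE	2	0.06
B_lateralis	PDE	33	0.6
C_simus	GC	5	0.4
B_asper_Car	GC	108	0.4
B_asper_Pac	GC	4	0.3
C_godmani	GC	32	0.3
A_picadoi	GC	13	0.1
A_mexicanus	GC	7	0.2
B_schlegelii	GC	0	0
B_lateralis	GC	1	0.02
C_simus	CVF	2	0.15
B_asper_Car	CVF	2	0.006
B_asper_Pac	CVF	0	0
C_godmani	CVF	1	0.01
A_picadoi	CVF	0	0
A_mexicanus	CVF	2	0.06
B_schlegelii	CVF	1	0.03
B_lateralis	CVF	0	0
C_simus	CRO	0	0
B_asper_Car	CRO	10	0.03
B_asper_Pac	CRO	4	0.3
C_godmani	CRO	2	0.02
A_picadoi	CRO	4	0.04
A_mexicanus	CRO	0	0
B_schlegelii	CRO	1	0.03
B_lateralis	CRO	1	0.02
C_simus	SARA	1	0.07
B_asper_Car	SARA	2	0.006
B_asper_Pac	SARA	0	0
C_godmani	SARA	0	0
A_picadoi	SARA	0	0
A_mexicanus	SARA	0	0
B_schlegelii	SARA	0	0
B_lateralis	SARA	0	0
C_simus	WAP	0	0
B_asper_Car	WAP	26	0.09
B_asper_Pac	WAP	0	0
C_godmani	WAP	0	0
A_picadoi	WAP	0	0
A_mexicanus	WAP	0	0
B_schlegelii	WAP	0	0
B_lateralis	WAP	0	0
C_simus	KUN	2	0.15
B_asper_Car	KUN	10	0.03
B_asper_Pac	KUN	3	0.2
C_godmani	KUN	0	0
A_picadoi	KUN	1	0.01
A_mexicanus	KUN	0	0
B_schlegelii	KUN	4	0.12
B_lateralis	KUN	1	0.02
C_simus	KAZ	0	0
B_asper_Car	KAZ	0	0
B_asper_Pac	KAZ	0	0
C_godmani	KAZ	0	0
A_picadoi	KAZ	0	0
A_mexicanus	KAZ	0	0
B_schlegelii	KAZ	9	0.3
B_lateralis	KAZ	12	0.2
C_simus	HYA	3	0.2
B_asper_Car	HYA	7	0.02
B_asper_Pac	HYA	1	0.07
C_godmani	HYA	4	0.04
A_picadoi	HYA	1	0.01
A_mexicanus	HYA	1	0.03
B_schlegelii	HYA	5	0.17
B_lateralis	HYA	2	0.03
C_simus	OHA	199	15
B_asper_Car	OHA	779	2.8
B_asper_Pac	OHA	165	11.9
C_godmani	OHA	256	2.6
A_picadoi	OHA	233	2.3
A_mexicanus	OHA	254	8.2
B_schlegelii	OHA	338	11.6
B_lateralis	OHA	188	3.3
C_simus	3FTx	169	12.7
B_asper_Car	3FTx	221	0.8
B_asper_Pac	3FTx	65	4.7
C_godmani	3FTx	63	0.6
A_picadoi	3FTx	43	0.4
A_mexicanus	3FTx	89	2.8
B_schlegelii	3FTx	104	3.6
B_lateralis	3FTx	91	1.6
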