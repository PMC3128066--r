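family	reads	pct
BPP	9231	14.8
CRISP	1066	1.7
CTL	1039	1.6
GF	789	1.2
LAO	2535	4
PLA2	7065	11.3
SVMP	26646	42.7
SP	10019	16
5NTase	374	0.6
PDE	119	0.2
GC	170	0.3
CVF	8	0.01
CRO	22	0.04
SARA	3	0.005
WAP	26	0.04
KUN	21	0.03
KAZ	21	0.03
HYA	24	0.04
OHA	2412	3.9
3FTx	845	1.3
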