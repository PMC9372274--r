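variable	term_id	count_all	count_c1	count_c2	count_c3
VSD	HP:9000101	512	482	9	21
PDA	HP:9000201	490	392	89	9
ACA	HP:9000202	281	267	1	13
ASD	HP:9000102	224	161	54	9
PFO	HP:9000103	211	167	44	0
RVH	HP:9000105	203	186	9	8
TOF	HP:9000108	122	116	1	5
TR	HP:9000301	99	33	64	2
LSVC	HP:9000206	93	82	3	8
SV	HP:9000106	45	30	8	7
Dextrocardia	HP:9000109	44	29	8	7
HRH	HP:9000107	44	7	35	2
CA	HP:9000104	25	11	6	8
TS	HP:9000302	19	4	15	0
TA	HP:9000303	18	2	12	4
MA	HP:9000304	3	1	1	1
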