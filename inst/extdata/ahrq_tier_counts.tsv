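dataset	review	tier0	tier1	tier2
drug	1	2544	183	41
drug	2	851	84	20
drug	3	310	92	16
drug	4	1120	363	146
drug	5	2072	302	42
drug	6	1218	279	100
drug	7	368	80	80
drug	8	393	88	41
drug	9	1915	48	15
drug	10	503	139	136
drug	11	1333	238	51
drug	12	1643	34	9
drug	13	3465	173	85
drug	14	671	218	24
drug	15	327	78	40
misc	1	616	38	12
misc	2	1733	273	92
misc	3	32308	421	198
misc	4	4949	413	83
misc	5	10	508	104
misc	6	505	130	34
misc	7	1261	1103	440
misc	8	14935	796	65
misc	9	10	329	21
misc	10	243	535	121
misc	11	1235	2329	365
misc	12	682	158	77
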