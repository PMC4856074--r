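chromosome	scaffold	n_mapped	n_overlapping	n_gm_overlapped	pct_gm_overlapped
I	scaffold_01	1065	1038	540	43.34
III	scaffold_02	842	828	449	40.20
V	scaffold_03	495	477	280	31.96
II+IV	scaffold_04	638	621	340	37.74
II	scaffold_05	659	638	364	41.65
VI	scaffold_06	558	540	285	36.26
VII	scaffold_07	485	476	259	36.79
VIII	scaffold_08	258	251	145	23.81
X	scaffold_09	289	270	153	26.33
IX	scaffold_10	313	308	172	32.09
XIII	scaffold_11	229	228	127	30.98
XII	scaffold_12	191	184	106	30.11
XI	scaffold_13	170	162	93	27.43
IV	scaffold_14	220	217	121	38.91
XI	scaffold_15	105	104	57	27.27
II	scaffold_16	97	95	48	25.40
XII	scaffold_17	67	63	44	25.43
IV	scaffold_18	33	33	22	28.21
VII	scaffold_19	34	33	13	21.31
ND	scaffold_22+29	4	4	2	17.15
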