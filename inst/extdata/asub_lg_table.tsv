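lg	length_cM	n_markers	n_distorted	largest_interval_cM
1	202	26	2	23
2	196	22	0	27
3	161	22	2	19
4	141	15	3	27
5	138	13	1	26
6	130	21	1	19
7	129	13	1	24
8	113	10	1	24
9	113	12	0	24
10	102	10	1	26
11	76	8	6	30
12	70	6	0	26
13	65	9	2	17
14	42	9	0	6
15	13	3	0	9
16	10	3	1	5
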