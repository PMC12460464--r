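site	n	age_mean	age_sd	male	female
CALTECH	32	26.79	9.6	25	7
CMU	27	26.59	5.58	21	6
KKI	55	10.1	1.31	42	13
LEUVEN_1	29	22.59	3.49	29	0
LEUVEN_2	35	14.16	1.4	27	8
MAX	57	26.16	11.98	50	7
NYU	179	15.39	6.59	142	37
OLIN	36	16.81	3.44	31	5
PITT	57	18.9	6.82	49	8
SBL	24	33	6.7	24	0
SDSU	32	14.35	1.85	25	7
TRINITY	42	16.84	3.63	42	0
UCLA_1	73	13.16	2.38	63	10
UCLA_2	26	12.49	1.5	24	2
UM_1	107	13.43	2.87	83	24
UM_2	35	15.96	3.27	33	2
USM	100	22.14	7.67	100	0
YALE	42	12.96	2.8	30	12
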