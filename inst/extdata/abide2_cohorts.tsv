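site	n	age_mean	age_sd	male	female
GU	104	10.68	1.62	69	35
KKI	197	10.34	1.27	128	69
NYU	27	6.78	1.07	24	3
OHSU	91	10.88	1.99	56	35
ONRC	43	23.33	3.85	31	12
SDSU	23	13.91	3.85	20	3
TCD	19	14.45	2.67	19	0
UCD	32	14.78	1.83	24	8
UCLA	32	10.7	2.36	26	6
USM	32	21.37	7.74	27	5
UMIA	23	9.8	2.02	17	6
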