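site	n	age_mean	age_sd	male	female
CBIC	287	10.75	3.73	188	99
SI	345	11.13	3.82	195	150
RU	753	9.92	0.42	501	252
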