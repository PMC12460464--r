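site	n	age_mean	age_sd	male	female
PIOP1	216	21.96	1.91	29	44
PIOP2	226	21.96	1.79	96	129
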