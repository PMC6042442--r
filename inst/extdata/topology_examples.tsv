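gene	degree_control	degree_treated	kcore_control	kcore_treated
G0S2	0	38	0	32
HSD11B1	0	38	0	32
HSD3B2	0	38	0	32
CXCL5	0	38	0	32
STAR	6	37	4	32
FA2H	9	31	7	28
DHCR7	23	38	21	32
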