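blastocyst_id	growth_group	expectation_group	maternal_age	gardner_score
H1	Group1	H	31	4BB
H2	Group1	H	42	4AA
H3	Group1	H	37	4AB
H4	Group1	H	29	4BB
H5	Group1	H	28	4BB
L1	Group2	L	38	4CC
L2	Group2	L	37	4CC
L3	Group2	L	39	4CC
L4	Group2	L	39	4CC
M1	Group3	M	40	4CB
M2	Group3	M	33	4CC
M3	Group3	M	39	4CC
M4	Group3	M	37	4BB
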