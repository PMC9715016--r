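par	chromosome	start	end
PAR1	X	60001	2699520
PAR1	Y	10001	2649520
PAR2	X	154931044	155260560
PAR2	Y	59034050	59363566
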