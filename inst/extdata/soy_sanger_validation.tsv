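set	class	concordant	discordant
A	AA	115	0
A	AB	3	1
A	BB	71	2
B	AA	111	0
B	AB	9	5
B	BB	67	0
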