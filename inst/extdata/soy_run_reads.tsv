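genotype	raw_reads	pct_processed	pct_mapped
Maple Donovan	540827	98.77	82.58
Toma	805460	98.75	85.58
S19-90	763541	98.77	84.64
Williams 82	877607	98.77	86.96
PS46RR	578458	98.76	85.23
TGx1989-53F	440636	98.76	83.47
TGx1990-67F	526300	98.76	85.60
Ocepara-4	1003014	98.76	84.64
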