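run	snp_count	mean_depth	description
standard_2M	6252	11.7	standard protocol, 2 M reads/sample
selective_AC_2M	8652	25.2	two selective bases (AC), 2 M reads/sample
selective_AC_1M	6846	16.0	two selective bases (AC), 1 M reads/sample (192-plex)
selective_AC_0.5M	5082	10.0	two selective bases (AC), 0.5 M reads/sample (384-plex)
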