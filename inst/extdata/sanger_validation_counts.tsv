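# Sanger verification outcome counts of a 767-locus random sample, by priority class
group	n_total	n_no_good_sequence	n_validated
A	89	17	72
B	233	43	158
C	390	73	244
D	55	9	31
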