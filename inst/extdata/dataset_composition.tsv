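class	source	total	below_min	above_max	kept
mRNA	human_reference_annotation	100291	374	23464	76453
lncRNA	human_reference_annotation	48351	291	3486	44574
lncRNA	lncrna_database_high_confidence	72803	0	8799	64004
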