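# restriction enzymes: cut_offset = bases from motif 5' end to the top-strand cut
name	motif	cut_offset
Hpy166II	GTNNAC	3
EcoRI	GAATTC	1
HindIII	AAGCTT	1
BamHI	GGATCC	1
TaqI	TCGA	1
DdeI	CTNAG	1
AluI	AGCT	2
DraI	TTTAAA	3
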