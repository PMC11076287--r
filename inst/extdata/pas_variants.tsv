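hexamer	usage_rank
AATAAA	1
ATTAAA	2
TATAAA	3
AGTAAA	4
AAGAAA	5
AATATA	6
AATACA	7
CATAAA	8
GATAAA	9
AATGAA	10
TTTAAA	11
ACTAAA	12
AATAGA	13
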