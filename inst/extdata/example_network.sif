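TF1	ac	GENE1
TF1	ac	GENE2
TF2	ac	GENE2
TF2	re	GENE3
TF3	du	GENE3
TF3	ac	GENE4
GENE2	ac	GENE5
GENE2	ac	GENE6
GENE4	re	GENE6
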