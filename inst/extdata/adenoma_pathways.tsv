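gene	pathway
TP53	p53_dna_damage
ATM	p53_dna_damage
ARID2	swi_snf
SMARCA4	swi_snf
PBRM1	swi_snf
BRD4	chromatin_other
KMT2D	chromatin_other
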