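gene	protein_change	count
SMARCA4	p.R1157W	8
SMARCA4	p.T910M	6
ERBB2	p.V842I	12
KRAS	p.G13D	851
TP53	p.R273C	322
ATM	p.R2443Q	6
FBXW7	p.R465C	57
ERBB3	p.V104M	3
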