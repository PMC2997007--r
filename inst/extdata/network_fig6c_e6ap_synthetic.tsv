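E6-AP	activate	Ub
Ub	activate	Rad23A
Rad23A	inhibit	p300
p300	activate	IL4
p300	activate	IRF1
p300	activate	GATA3
p300	activate	NFATC3
p300	activate	PTGS2
Rad23A	inhibit	RelA
RelA	activate	CCR2
RelA	activate	CCR3
RelA	activate	CXCR4
RelA	activate	CLEC1A
E6-AP	inhibit	p53
p53	inhibit	BCL2
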