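Ub	activate	Rad23A
Rad23A	inhibit	p300
p300	activate	RelA
RelA	activate	TNF
RelA	activate	IL1B
RelA	activate	CCL4
RelA	activate	CCL8
RelA	activate	PTGS2
RelA	activate	IL2RA
Rad23A	inhibit	HIF1A
HIF1A	activate	SELP
p300	activate	STAT1
p300	activate	NFATC3
p300	activate	GATA3
GATA3	activate	STAT6
STAT6	activate	IL4
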