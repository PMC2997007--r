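UBE2L3	activate	E6-AP
E6-AP	activate	IKKbeta
IKKbeta	activate	NF-kB
NF-kB	activate	PTGS2
NF-kB	activate	IL2RA
NF-kB	activate	SELP
NF-kB	activate	LILRB4
NF-kB	activate	IRF4
IRF4	activate	ETS1
E6-AP	activate	JAK1
JAK1	activate	STAT1
STAT1	activate	TAP2
STAT1	activate	CCR2
E6-AP	activate	Calcineurin
Calcineurin	activate	NFATC3
NFATC3	activate	IL4
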