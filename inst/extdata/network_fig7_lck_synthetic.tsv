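Csk	inhibit	Lck
Lck	activate	ZAP70
ZAP70	activate	LAT
LAT	activate	PLCgamma1
PLCgamma1	activate	CCL2
PLCgamma1	activate	SLAMF1
PLCgamma1	activate	ANXA3
PLCgamma1	activate	ITK
Lck	activate	PI3K
PI3K	activate	Akt
Akt	activate	NF-kB
NF-kB	activate	CD80
NF-kB	activate	IL8RB
NF-kB	activate	IGSF6
NF-kB	activate	LIFR
Lck	activate	JAK3
JAK3	activate	STAT5
STAT5	activate	IL7R
STAT5	activate	MPO
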