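LPS	activate	TLR4
TLR4	activate	Raf-1
Raf-1	activate	MEK1
MEK1	activate	ERK1/2
DUSP6	inhibit	ERK1/2
ERK1/2	activate	Elk-1
Elk-1	activate	CSF1
Elk-1	activate	SHC1
ERK1/2	activate	c-Fos
c-Fos	activate	AP-1
AP-1	activate	IL5
AP-1	activate	TNFSF14
ERK1/2	activate	RSK1
RSK1	activate	CREB
CREB	activate	CD14
CREB	activate	ITGAX
CREB	activate	C/EBPbeta
C/EBPbeta	activate	CXCR4
ERK1/2	activate	MSK1
MSK1	activate	NF-kB
NF-kB	activate	MADCAM1
NF-kB	activate	CCR1
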