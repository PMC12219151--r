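set	gene
ar_signature	KLK3
ar_signature	KLK2
ar_signature	NKX3-1
ar_signature	TMPRSS2
ar_signature	FKBP5
ar_signature	PLPP1
ar_signature	PMEPA1
ar_signature	PART1
ar_signature	ALDH1A3
ar_signature	STEAP4
ne1	SYP
ne1	CHGA
ne1	CHGB
ne1	ENO2
ne1	NCAM1
ne1	ASCL1
ne1	INSM1
ne1	SCG3
ne1	PCSK1
ne1	SCN3A
bmp4	BMP4
bmp4	ID1
bmp4	ID2
bmp4	ID3
bmp4	SMAD6
bmp4	SMAD8
bmp4	DLX3
bmp4	SKIL
fgf	FGF1
fgf	FGF8
fgf	FGF9
fgf	FGFBP1
fgf	FGFR1
fgf	FGFR2
fgf	FGFR3
fgf	FGFR4
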