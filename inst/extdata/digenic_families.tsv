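patient_id	etiology	variant	zygosity	acmg
HTP070	IPAH	BMPR2:NM_001204.6:c.77-5_77-2delTTTA	.	P
HTP070	IPAH	NOTCH3:NM_000435.2:c.181C>T:p.(Arg61Trp)	.	VUS
HTP081	IPAH	NOTCH3:NM_000435.2:c.1964A>G:p.(Asn655Ser)	.	VUS
HTP466	IPAH	ABCC8:NM_000352.4:c.3976G>A:p.(Glu1326Lys)	.	LP
HTP466	IPAH	NOTCH3:NM_000435.2:c.6532C>T:p.(Pro2178Ser)	.	VUS
HTP474	CHD	ABCC8:NM_000352.4(ABCC8):c.3394G>A:p.(Asp1132Asn)	.	VUS
HTP474	CHD	SARS2:NM_017827.3:c.136G>A:p.(Glu46Lys)	.	VUS
HTP611	CHD	TBX4:NM_018488.3:c.1018C>T:p.(Arg340 *)	.	P
HTP611	CHD	SMAD1:NM_005900.2:c.738G>C:p.(Met246Ile)	.	VUS
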