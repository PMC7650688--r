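patient_id	etiology	variant	zygosity	acmg
HTP501	CHD	CPS1:NM_001122633.2(CPS1):c.3047C>T:p.(Thr1016Met)	Hom	VUS
HTP536	CHD	BMPR2:NM_001204.6:c.2674delG: p.(Glu892Asnfs*4)	Het	P
HTP541	CHD	BMPR2:NM_001204.6:c.2674delG: p.(Glu892Asnfs*4)	Het	P
HTP474	CHD	ABCC8:NM_000352.4(ABCC8):c.3394G>A:p.(Asp1132Asn)	Het	VUS
HTP474	CHD	SARS2:NM_017827.3:c.136G>A:p.(Glu46Lys)	Het	VUS
HTP558	CHD	SMAD5:NM_001001420.2:c.763A>G:p.(Ile255Val)	Het	VUS
HTP262	CHD	NOTCH3:NM_000435.3:c.6097C>G:p.(Pro2033Ala)	Het	VUS
HTP472	CHD	CPS1:NM_001122633.2:c.1036G>A:p.(Ala346Thr)	Het	VUS
HTP611	CHD	TBX4:NM_018488.3:c.1018C>T:p.(Arg340*)	Het	P
HTP611	CHD	SMAD1:NM_005900.2:c.738G>C:p.(Met246Ile)	Het	VUS
HTP551	CTD	GDF2:NM_016204:c.642G>A:p.(Trp214*)	Het	VUS
HTP355	CTD	CPS1:NM_001875.4:c.4252C>T:p.(Pro1418Ser)	Het	VUS
HTP452	CTD	NOTCH3:NM_000435:c.5203G>A:p.(Glu1735Lys)	Het	VUS
HTP564	CTD	TBX4:NM_018488.2:c.1112dupC:p.(Pro372Serfs*14)	Het	P
HTP78	CTD	ABCC8:NM_000352.3:c.2694+1G>A	Het	VUS
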