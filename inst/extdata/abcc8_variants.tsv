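patient_id	etiology	variant	zygosity	acmg
HTP114	IPAH	ABCC8:NM_000352.4:c.1643C>T:p.(Thr548Met)	.	.
HTP88	IPAH	ABCC8:NM_000352:exon26:c.3288_3289del:p.(His1097Profs*16)	.	.
HTP151	IPAH	ABCC8:NM_000352.4:c.3238G>A:p.(Val1080Ile)	.	.
HTP159	IPAH	ABCC8:NM_000352.4:c.2422C>A:p.(Gln808Lys)	.	.
HTP162	IPAH	ABCC8:NM_000352.4:c.1429G>A:p.(Val477Met)	.	.
HTP466	IPAH	ABCC8:NM_000352.4:c.3976G>A:p.Glu1326Lys	.	.
HTP37	IPAH	ABCC8:NM_000352.3:c.579+5G>A	.	.
HTP78	CREST-PAH	ABCC8:NM_000352.3:c.2694+1G>A	.	.
HTP474	CHD	ABCC8:NM_000352.4:c.3394G>A:p.Asp1132Asn	.	.
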