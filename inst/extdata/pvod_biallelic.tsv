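patient_id	etiology	variant	zygosity	acmg
PVOD01	PVOD	EIF2AK4:NM_001013703.3:c.3344C>T:p.(Pro1115Leu)	Hom	P
PVOD02	PVOD	EIF2AK4:NM_001013703.3:c.3766C>T:p.(Arg1256*)	Het	P
PVOD02	PVOD	EIF2AK4:NM_001013703.3:c.4392dup:p.(Lys1465*)	Het	P
PVOD03	PVOD	EIF2AK4:NM_001013703.3:c.3766C>T:p.(Arg1256*)	Het	P
PVOD03	PVOD	EIF2AK4:NM_001013703.3:c.4392dup:p.(Lys1465*)	Het	P
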