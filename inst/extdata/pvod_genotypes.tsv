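individual_id	variant	zygosity
PVOD02_fa	EIF2AK4:NM_001013703.3:c.3766C>T:p.(Arg1256*)	het
PVOD02_mo	EIF2AK4:NM_001013703.3:c.4392dup:p.(Lys1465*)	het
PVOD02	EIF2AK4:NM_001013703.3:c.3766C>T:p.(Arg1256*)	het
PVOD02	EIF2AK4:NM_001013703.3:c.4392dup:p.(Lys1465*)	het
PVOD03	EIF2AK4:NM_001013703.3:c.3766C>T:p.(Arg1256*)	het
PVOD03	EIF2AK4:NM_001013703.3:c.4392dup:p.(Lys1465*)	het
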