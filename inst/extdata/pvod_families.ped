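FAM_PVOD02	PVOD02_fa	0	0	1	1
FAM_PVOD02	PVOD02_mo	0	0	2	1
FAM_PVOD02	PVOD02	PVOD02_fa	PVOD02_mo	1	2
FAM_PVOD02	PVOD03	PVOD02_fa	PVOD02_mo	2	2
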