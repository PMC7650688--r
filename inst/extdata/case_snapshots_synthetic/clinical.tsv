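chrom	pos	ref	alt	assertion
ctg_BMPR2	470	AATTT	A	pathogenic_reported
ctg_TBX4	1418	C	T	pathogenic_reported
ctg_BMPR2	4273	CG	C	pathogenic_reported
ctg_TBX4	1808	T	TC	pathogenic_reported
ctg_EIF2AK4	4044	C	T	pathogenic_reported
ctg_EIF2AK4	4766	C	T	pathogenic_reported
ctg_EIF2AK4	5389	C	CA	pathogenic_reported
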