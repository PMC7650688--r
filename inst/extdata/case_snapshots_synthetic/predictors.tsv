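chrom	pos	ref	alt	n_deleterious	n_total	cadd_like
ctg_NOTCH3	281	C	T	3	10	15
ctg_NOTCH3	2364	A	G	3	10	15
ctg_ABCC8	5876	G	A	3	10	15
ctg_NOTCH3	8432	C	T	3	10	15
ctg_ABCC8	4994	G	A	3	10	15
ctg_SARS2	236	G	A	3	10	15
ctg_SMAD1	1138	G	C	2	11	15
ctg_ABCC8	2343	C	T	3	10	15
ctg_ABCC8	4538	G	A	3	10	15
ctg_ABCC8	3422	C	A	3	10	15
ctg_ABCC8	2129	G	A	3	10	15
ctg_CPS1	3747	C	T	3	10	15
ctg_SMAD5	1163	A	G	3	10	15
ctg_NOTCH3	7997	C	G	3	10	15
ctg_CPS1	1136	G	A	3	10	15
ctg_CPS1	4952	C	T	3	10	15
ctg_NOTCH3	6803	G	A	3	10	15
ctg_EIF2AK4	4044	C	T	3	10	15
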