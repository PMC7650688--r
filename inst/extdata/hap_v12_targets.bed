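ctg_ABCC8	75	704	ABCC8	ABCC8_ex01
ctg_ABCC8	954	1625	ABCC8	ABCC8_ex02
ctg_ABCC8	1875	2525	ABCC8	ABCC8_ex03
ctg_ABCC8	2775	3719	ABCC8	ABCC8_ex04
ctg_ABCC8	3969	4625	ABCC8	ABCC8_ex05
ctg_ABCC8	4875	5525	ABCC8	ABCC8_ex06
ctg_ABCC8	5775	6325	ABCC8	ABCC8_ex07
ctg_ABCC8	6575	6974	ABCC8	ABCC8_ex08
ctg_ACVRL1	75	625	ACVRL1	ACVRL1_ex01
ctg_ACVRL1	875	1937	ACVRL1	ACVRL1_ex02
ctg_BMPR1B	75	825	BMPR1B	BMPR1B_ex01
ctg_BMPR1B	1075	1934	BMPR1B	BMPR1B_ex02
ctg_BMPR2	75	201	BMPR2	BMPR2_ex01
ctg_BMPR2	451	1025	BMPR2	BMPR2_ex02
ctg_BMPR2	1275	1925	BMPR2	BMPR2_ex03
ctg_BMPR2	2175	2925	BMPR2	BMPR2_ex04
ctg_BMPR2	3175	3825	BMPR2	BMPR2_ex05
ctg_BMPR2	4075	4739	BMPR2	BMPR2_ex06
ctg_CAV1	75	662	CAV1	CAV1_ex01
ctg_CBLN2	75	425	CBLN2	CBLN2_ex01
ctg_CBLN2	675	1004	CBLN2	CBLN2_ex02
ctg_CPS1	75	1625	CPS1	CPS1_ex01
ctg_CPS1	1875	3425	CPS1	CPS1_ex02
ctg_CPS1	3675	5228	CPS1	CPS1_ex03
ctg_EIF2AK4	75	1325	EIF2AK4	EIF2AK4_ex01
ctg_EIF2AK4	1575	2825	EIF2AK4	EIF2AK4_ex02
ctg_EIF2AK4	3075	4325	EIF2AK4	EIF2AK4_ex03
ctg_EIF2AK4	4575	5924	EIF2AK4	EIF2AK4_ex04
ctg_ENG	75	1025	ENG	ENG_ex01
ctg_ENG	1275	2402	ENG	ENG_ex02
ctg_GDF2	75	525	GDF2	GDF2_ex01
ctg_GDF2	775	1715	GDF2	GDF2_ex02
ctg_KCNA5	75	1967	KCNA5	KCNA5_ex01
ctg_KCNK3	75	1310	KCNK3	KCNK3_ex01
ctg_MMACHC	75	974	MMACHC	MMACHC_ex01
ctg_NOTCH3	75	1125	NOTCH3	NOTCH3_ex01
ctg_NOTCH3	1375	2425	NOTCH3	NOTCH3_ex02
ctg_NOTCH3	2675	3725	NOTCH3	NOTCH3_ex03
ctg_NOTCH3	3975	5025	NOTCH3	NOTCH3_ex04
ctg_NOTCH3	5275	6325	NOTCH3	NOTCH3_ex05
ctg_NOTCH3	6575	7625	NOTCH3	NOTCH3_ex06
ctg_NOTCH3	7875	8891	NOTCH3	NOTCH3_ex07
ctg_SARS2	75	925	SARS2	SARS2_ex01
ctg_SARS2	1175	1982	SARS2	SARS2_ex02
ctg_SMAD1	75	825	SMAD1	SMAD1_ex01
ctg_SMAD1	1075	1823	SMAD1	SMAD1_ex02
ctg_SMAD4	75	925	SMAD4	SMAD4_ex01
ctg_SMAD4	1175	2084	SMAD4	SMAD4_ex02
ctg_SMAD5	75	825	SMAD5	SMAD5_ex01
ctg_SMAD5	1075	1823	SMAD5	SMAD5_ex02
ctg_SMAD9	75	825	SMAD9	SMAD9_ex01
ctg_SMAD9	1075	1829	SMAD9	SMAD9_ex02
ctg_TBX4	75	625	TBX4	TBX4_ex01
ctg_TBX4	875	1525	TBX4	TBX4_ex02
ctg_TBX4	1775	2366	TBX4	TBX4_ex03
ctg_TOPBP1	75	1625	TOPBP1	TOPBP1_ex01
ctg_TOPBP1	1875	3425	TOPBP1	TOPBP1_ex02
ctg_TOPBP1	3675	5321	TOPBP1	TOPBP1_ex03
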