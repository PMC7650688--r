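chrom	pos	ref	alt	source	af
ctg_TBX4	1418	C	T	gnomad_exomes_like	2.81e-05
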