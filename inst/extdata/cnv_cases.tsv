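patient_id	etiology	gene	label	kind
HTP081	IPAH	BMPR2	BMPR2_ex02	gain
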