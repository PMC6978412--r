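term_id	ontology	n_annotated	n_eval	n_pos_eval	auroc	auprc	method	size_bin
TA	BP	4	3	1	1	1	correlation	NA
TB	MF	4	3	2	1	1	correlation	NA
TD	BP	3	3	0	NA	NA	correlation	NA
TA	BP	4	3	1	1	1	domain	NA
TB	MF	4	3	2	1	1	domain	NA
TD	BP	3	3	0	NA	NA	domain	NA
TA	BP	4	3	1	1	1	combination	NA
TB	MF	4	0	0	NA	NA	combination	NA
TD	BP	3	3	0	NA	NA	combination	NA
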