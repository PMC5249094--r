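cohort	phenotype	n_tested	n_wild	n_het	n_hom_mut
NAD-affected Papillon	affected	3	0	0	3
NAD-affected Papillon x Chihuahua mix	affected	1	0	0	1
NAD carrier Papillon	unaffected	2	0	2	0
Unaffected Papillon	unaffected	82	82	0	0
Unaffected Chihuahua	unaffected	49	49	0	0
Unaffected Papillon x Chihuahua mix	unaffected	1	1	0	0
Unaffected other breeds	unaffected	118	118	0	0
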