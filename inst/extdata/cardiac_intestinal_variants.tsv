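sample_id	tissue	patient_id	position	ref	alt	var_class	zygosity	het_level	confirmed	region
caseB.g1	epithelial_gland	caseB	10492	T	C	SNV	homoplasmic	NA	TRUE	MT-ND4L
caseB.g2	epithelial_gland	caseB	10492	T	C	SNV	homoplasmic	NA	TRUE	MT-ND4L
caseB.g3	epithelial_gland	caseB	NA	NA	NA	none	NA	NA	NA	NA
caseB.stroma	stroma	caseB	NA	NA	NA	none	NA	NA	NA	NA
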