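sample_id	tissue	patient_id	position	ref	alt	var_class	zygosity	het_level	confirmed	region
caseC.g2	epithelial_gland	caseC	2217	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g2	epithelial_gland	caseC	2283	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g3	epithelial_gland	caseC	2217	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g3	epithelial_gland	caseC	2283	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g4	epithelial_gland	caseC	2217	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g4	epithelial_gland	caseC	2283	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g5	epithelial_gland	caseC	2217	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g5	epithelial_gland	caseC	2283	T	C	SNV	homoplasmic	NA	TRUE	MT-RNR2
caseC.g1	epithelial_gland	caseC	NA	NA	NA	none	NA	NA	NA	NA
caseC.g6	epithelial_gland	caseC	NA	NA	NA	none	NA	NA	NA	NA
caseC.stroma	stroma	caseC	NA	NA	NA	none	NA	NA	NA	NA
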