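sample_id	tissue	patient_id	position	ref	alt	var_class	zygosity	het_level	confirmed	region
caseA.g1	epithelial_gland	caseA	303	C	Cins	insertion	homoplasmic	NA	TRUE	MT-OHR
caseA.g2	epithelial_gland	caseA	303	C	Cins	insertion	homoplasmic	NA	TRUE	MT-OHR
caseA.g3	epithelial_gland	caseA	303	C	Cins	insertion	homoplasmic	NA	TRUE	MT-OHR
caseA.g4	epithelial_gland	caseA	303	C	Cins	insertion	homoplasmic	NA	TRUE	MT-OHR
caseA.g5	epithelial_gland	caseA	303	C	Cins	insertion	homoplasmic	NA	TRUE	MT-OHR
caseA.g6	epithelial_gland	caseA	NA	NA	NA	none	NA	NA	NA	NA
caseA.stroma	stroma	caseA	NA	NA	NA	none	NA	NA	NA	NA
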