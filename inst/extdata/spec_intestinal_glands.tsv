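gland_id	biopsy_id	patient_id	group	marker:hk_atpase	marker:pepsinogen	marker:muc5ac	marker:muc2	marker:hd5	marker:hd6
caseC.g1	caseC.b1	caseC	BE	neg	neg	neg	pos	pos	na
caseC.g2	caseC.b1	caseC	BE	neg	neg	neg	pos	pos	na
caseC.g3	caseC.b1	caseC	BE	neg	neg	neg	pos	pos	na
caseC.g4	caseC.b1	caseC	BE	neg	neg	low	pos	neg	na
caseC.g5	caseC.b1	caseC	BE	neg	neg	pos	pos	neg	na
caseC.g6	caseC.b1	caseC	BE	neg	neg	pos	pos	neg	na
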