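gland_id	biopsy_id	patient_id	group	marker:hk_atpase	marker:pepsinogen	marker:muc5ac	marker:muc2	marker:hd5	marker:hd6
caseB.g1	caseB.b1	caseB	BE	neg	neg	neg	pos	na	na
caseB.g2	caseB.b1	caseB	BE	neg	neg	pos	neg	na	na
caseB.g3	caseB.b1	caseB	BE	neg	neg	pos	pos	na	na
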