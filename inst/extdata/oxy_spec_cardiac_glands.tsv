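gland_id	biopsy_id	patient_id	group	marker:hk_atpase	marker:pepsinogen	marker:muc5ac	marker:muc2	marker:hd5	marker:hd6
caseA.g1	caseA.b1	caseA	BE	pos	neg	pos	neg	na	na
caseA.g2	caseA.b1	caseA	BE	pos	neg	neg	neg	na	na
caseA.g3	caseA.b1	caseA	BE	neg	neg	pos	pos	na	na
caseA.g4	caseA.b1	caseA	BE	neg	neg	pos	pos	na	na
caseA.g5	caseA.b1	caseA	BE	neg	neg	pos	neg	na	na
caseA.g6	caseA.b1	caseA	BE	neg	neg	pos	neg	na	na
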