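study_id,tail,head,criterion,verdict,rationale,reference,reviewer,confidence,timestamp
idag,adol_sex,parental_alc_hist,temporality,yes,re-assessed on the I-DAG: still no mechanism to parental history,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,parental_alc_hist,face_validity,yes,re-assessed on the I-DAG: still no mechanism to parental history,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,parental_alc_hist,recourse_to_theory,unknown,re-assessed on the I-DAG: still no mechanism to parental history,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,parental_alc_hist,counterfactual,no,re-assessed on the I-DAG: still no mechanism to parental history,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,parental_alc_hist,adol_sex,temporality,yes,implausible influence on sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,parental_alc_hist,adol_sex,face_validity,no,implausible influence on sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,alc_initiation,temporality,yes,no initiation-age contrast between counterfactual sexes supported,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,alc_initiation,face_validity,yes,no initiation-age contrast between counterfactual sexes supported,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,alc_initiation,recourse_to_theory,unknown,no initiation-age contrast between counterfactual sexes supported,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,alc_initiation,counterfactual,no,no initiation-age contrast between counterfactual sexes supported,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_sex,temporality,yes,initiation cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_sex,face_validity,no,initiation cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,family_structure,temporality,yes,relationship between family structure and adolescent sex rejected on the I-DAG,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,family_structure,face_validity,yes,relationship between family structure and adolescent sex rejected on the I-DAG,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,family_structure,recourse_to_theory,unknown,relationship between family structure and adolescent sex rejected on the I-DAG,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_sex,family_structure,counterfactual,no,relationship between family structure and adolescent sex rejected on the I-DAG,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_sex,temporality,yes,family structure cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_sex,face_validity,no,family structure cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_substance,alc_initiation,temporality,no,alcohol initiation precedes wider adolescent substance involvement,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_substance,temporality,yes,age of alcohol initiation hypothesised to cause other substance use,early-onset literature,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_substance,face_validity,yes,age of alcohol initiation hypothesised to cause other substance use,early-onset literature,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_substance,recourse_to_theory,yes,age of alcohol initiation hypothesised to cause other substance use,early-onset literature,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,adol_substance,counterfactual,yes,age of alcohol initiation hypothesised to cause other substance use,early-onset literature,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_substance,family_structure,temporality,yes,adolescent substance use not posited to change family structure,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_substance,family_structure,face_validity,yes,adolescent substance use not posited to change family structure,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_substance,family_structure,recourse_to_theory,unknown,adolescent substance use not posited to change family structure,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,adol_substance,family_structure,counterfactual,no,adolescent substance use not posited to change family structure,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_substance,temporality,yes,association read as running through parental drinking and initiation,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_substance,face_validity,yes,association read as running through parental drinking and initiation,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_substance,recourse_to_theory,yes,association read as running through parental drinking and initiation,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,adol_substance,counterfactual,no,association read as running through parental drinking and initiation,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,family_structure,temporality,yes,no support for initiation driving family dissolution,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,family_structure,face_validity,yes,no support for initiation driving family dissolution,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,family_structure,recourse_to_theory,no,no support for initiation driving family dissolution,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,alc_initiation,family_structure,counterfactual,no,no support for initiation driving family dissolution,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,alc_initiation,temporality,yes,association read as confounded by parental drinking rather than direct,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,alc_initiation,face_validity,yes,association read as confounded by parental drinking rather than direct,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,alc_initiation,recourse_to_theory,yes,association read as confounded by parental drinking rather than direct,,reviewer_1,normal,2019-01-01T00:00:00Z
idag,family_structure,alc_initiation,counterfactual,no,association read as confounded by parental drinking rather than direct,,reviewer_1,normal,2019-01-01T00:00:00Z
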