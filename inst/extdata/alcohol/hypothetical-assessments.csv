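study_id,tail,head,criterion,verdict,rationale,reference,reviewer,confidence,timestamp
hypothetical,parental_alc_hist,adol_alc,temporality,yes,parental drinking history precedes and plausibly shapes offspring drinking,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_alc,face_validity,yes,parental drinking history precedes and plausibly shapes offspring drinking,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_alc,recourse_to_theory,yes,parental drinking history precedes and plausibly shapes offspring drinking,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_alc,counterfactual,yes,parental drinking history precedes and plausibly shapes offspring drinking,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,parental_alc_hist,temporality,no,offspring adolescent drinking cannot precede historical parental use,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,parental_alc_hist,temporality,yes,no mechanism from offspring sex to parental drinking history expected under the counterfactual contrast,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,parental_alc_hist,face_validity,yes,no mechanism from offspring sex to parental drinking history expected under the counterfactual contrast,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,parental_alc_hist,recourse_to_theory,unknown,no mechanism from offspring sex to parental drinking history expected under the counterfactual contrast,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,parental_alc_hist,counterfactual,no,no mechanism from offspring sex to parental drinking history expected under the counterfactual contrast,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_sex,temporality,yes,implausible that historical parental alcohol use influences sex assignment despite temporal ordering,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_sex,face_validity,no,implausible that historical parental alcohol use influences sex assignment despite temporal ordering,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_alc,temporality,yes,potential outcomes for drinking frequency expected to differ when all set male vs all set female,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_alc,face_validity,yes,potential outcomes for drinking frequency expected to differ when all set male vs all set female,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_alc,recourse_to_theory,unknown,potential outcomes for drinking frequency expected to differ when all set male vs all set female,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_alc,counterfactual,yes,potential outcomes for drinking frequency expected to differ when all set male vs all set female,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_sex,temporality,yes,drinking cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_sex,face_validity,no,drinking cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,parental_alc_hist,temporality,no,adolescent substance use cannot precede historical parental alcohol use,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_substance,temporality,yes,parental drinking history plausibly causes wider offspring substance use,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_substance,face_validity,yes,parental drinking history plausibly causes wider offspring substance use,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_substance,recourse_to_theory,yes,parental drinking history plausibly causes wider offspring substance use,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,parental_alc_hist,adol_substance,counterfactual,yes,parental drinking history plausibly causes wider offspring substance use,social learning theory,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_alc,temporality,yes,substance involvement expected to raise drinking frequency under the counterfactual contrast,gateway/common liability accounts,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_alc,face_validity,yes,substance involvement expected to raise drinking frequency under the counterfactual contrast,gateway/common liability accounts,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_alc,recourse_to_theory,yes,substance involvement expected to raise drinking frequency under the counterfactual contrast,gateway/common liability accounts,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_alc,counterfactual,yes,substance involvement expected to raise drinking frequency under the counterfactual contrast,gateway/common liability accounts,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_substance,temporality,yes,with the study's measurement order no reverse effect is posited,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_substance,face_validity,yes,with the study's measurement order no reverse effect is posited,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_substance,recourse_to_theory,yes,with the study's measurement order no reverse effect is posited,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_alc,adol_substance,counterfactual,no,with the study's measurement order no reverse effect is posited,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_substance,temporality,yes,sex differences in adolescent substance involvement are well documented,risk-behaviour epidemiology,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_substance,face_validity,yes,sex differences in adolescent substance involvement are well documented,risk-behaviour epidemiology,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_substance,recourse_to_theory,yes,sex differences in adolescent substance involvement are well documented,risk-behaviour epidemiology,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_sex,adol_substance,counterfactual,yes,sex differences in adolescent substance involvement are well documented,risk-behaviour epidemiology,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_sex,temporality,yes,substance use cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
hypothetical,adol_substance,adol_sex,face_validity,no,substance use cannot influence sex assignment,,reviewer_1,normal,2019-01-01T00:00:00Z
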