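study_id: hypothetical
citation: >-
  Hypothetical study of historical parental alcohol use and offspring
  adolescent alcohol use, controlling for adolescent sex and adolescent
  substance use.
exposures:
- parental_alc_hist
outcomes:
- adol_alc
controls:
- adol_sex
- adol_substance
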