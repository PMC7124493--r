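study_id: seljamo
citation: >-
  Seljamo S, Aromaa M, Koivusilta L, et al. Alcohol use in families: a
  15-year prospective follow-up study. Multiple regression of adolescent
  alcohol use on early adolescent alcohol initiation, family structure,
  adolescent sex and historical parental alcohol use.
exposures:
- parental_alc_hist
outcomes:
- adol_alc
controls:
- alc_initiation
- family_structure
- adol_sex
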