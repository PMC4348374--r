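# All-cause mortality rate (per person-year), Tunisia circa 1997-2005, by sex
# and age band.
# source: assumption -- age/sex-specific all-cause mortality is not published
# with the survey tables. This Gompertz-like placeholder schedule is
# calibrated a priori so the implied 1997 crude 25+ death rates are plausible
# for Tunisia (about 10 per 1000 men, 8 per 1000 women aged 25+).
# Substitute official INS life tables for serious use.
age_band,men,women
25-34,0.0018,0.0010
35-44,0.0025,0.0016
45-54,0.0055,0.0035
55-64,0.0130,0.0085
65-74,0.0320,0.0240
75+,0.0950,0.0850
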