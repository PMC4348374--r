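# T2D prevalence (%), Tunisia 1997, by sex and age band, as printed in the
# 1996/97 national nutrition survey table (fasting plasma glucose >= 7 mmol/l
# or previous diagnosis).
# source: survey_table
age_band,men,women
25-34,8.0,6.8
35-44,8.6,8.6
45-54,15.6,13.6
55-64,18.4,21.0
65-74,15.3,22.2
75+,23.5,26.4
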