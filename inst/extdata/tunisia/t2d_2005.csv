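# T2D prevalence (%), Tunisia 2005 (TAHINA), by sex and age band, as printed.
# 25-34 and 75+ were not covered by the survey; the printed cells carry the
# published imputed values.
# source: survey_table
age_band,men,women
25-34,13.9,9.2
35-44,15.9,11.8
45-54,17.2,14.8
55-64,22.6,21.9
65-74,16.9,21.3
75+,18.7,16.8
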