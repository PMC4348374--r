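# Current-smoking prevalence (%), Tunisia 1997, by sex and age band.
# source: survey_table
age_band,men,women
25-34,58.8,0.9
35-44,49.7,1.9
45-54,43.4,2.0
55-64,33.4,2.0
65-74,33.4,1.4
75+,33.6,0.9
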