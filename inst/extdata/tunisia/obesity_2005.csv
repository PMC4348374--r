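# Obesity prevalence (%), Tunisia 2005 (TAHINA), by sex and age band.
# source: survey_table
age_band,men,women
25-34,7.3,17.3
35-44,14.4,33.7
45-54,20.4,45.5
55-64,17.0,35.2
65-74,10.4,28.1
75+,10.0,19.9
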