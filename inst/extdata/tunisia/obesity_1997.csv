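# Obesity prevalence (%), Tunisia 1997, by sex and age band.
# source: survey_table
age_band,men,women
25-34,4.9,17.3
35-44,11.3,28.8
45-54,8.3,38.8
55-64,7.4,32.5
65-74,8.2,25.9
75+,10.0,15.7
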