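# Tunisian population aged 25+, 1997, thousand persons, by sex and age band.
# source: survey_table (1996/97 national surveys / census-based estimates)
age_band,men,women
25-34,733,751
35-44,549,546
45-54,318,329
55-64,261,264
65-74,174,201
75+,90,85
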