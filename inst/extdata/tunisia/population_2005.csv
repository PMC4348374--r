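# Tunisian population aged 25+, 2005, thousand persons, by sex and age band.
# source: survey_table (2005 TAHINA survey / census-based estimates)
age_band,men,women
25-34,798,849
35-44,671,706
45-54,522,516
55-64,282,299
65-74,226,225
75+,126,119
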