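# Current-smoking prevalence (%), Tunisia 2005 (TAHINA), by sex and age band.
# Transcribed verbatim from the printed table (column order: men then women
# within each block). NOTE: the printed (women, 25-34) cell of 6.8 is
# inconsistent with the printed women's total of 2.5 (the crude band-weighted
# total of the cells below is 3.65); it is carried as printed.
# source: survey_table
age_band,men,women
25-34,50.0,6.8
35-44,53.8,2.6
45-54,47.0,2.0
55-64,42.4,2.0
65-74,26.2,2.2
75+,18.8,1.4
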