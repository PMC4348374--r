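# Tunisian population aged 25+, 2027 projection, thousand persons.
# source: assumption -- only the per-sex totals (3879 men, 4117 women) and
# aggregate shares (25-34 falling to 22.9%, 65+ rising to 16%) are published;
# the per-band split below is constructed to satisfy those aggregates with a
# smooth age distribution. Substitute official INS projections if available.
age_band,men,women
25-34,888.3,942.8
35-44,868.9,922.2
45-54,783.6,831.6
55-64,717.6,761.6
65-74,407.3,432.3
75+,213.3,226.5
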