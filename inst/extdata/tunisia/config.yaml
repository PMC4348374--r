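# Input manifest for the Tunisian study fixture.
horizon_year: 2027
anchors:
  - year: 1997
    population: population_1997.csv
    t2d: t2d_1997.csv
    obesity: obesity_1997.csv
    smoking: smoking_1997.csv
  - year: 2005
    population: population_2005.csv
    t2d: t2d_2005.csv
    obesity: obesity_2005.csv
    smoking: smoking_2005.csv
demography:
  1997: population_1997.csv
  2005: population_2005.csv
  2027: population_2027.csv
mortality: mortality.csv
parameters: parameters.yaml
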