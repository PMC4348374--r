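# Epidemiological parameters.
# source: assumption -- the relative-mortality schedule (Verona-study
# quantity) and the incidence relative risks are not published with the
# model; these are literature-informed defaults. Bounds are used by the
# analysis of extremes.
rr_mortality:
  "25-34": 3.0
  "35-44": 2.8
  "45-54": 2.3
  "55-64": 1.9
  "65-74": 1.6
  "75+": 1.4
rr_incidence:
  obese: 3.0
  smoker: 1.4
  obese_smoker: 4.2
bounds_rel: 0.25
# Secular annual relative decline of all-cause mortality (demographic
# consistency with the census-based projections; source: assumption).
mortality_improvement: 0.015
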