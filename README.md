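# t2dmarkov

Multi-state Markov projection of type 2 diabetes (T2D) prevalence from
demographic change plus obesity and smoking trends.

Most diabetes projections extrapolate demography alone. This package
implements the alternative used for several middle-income countries: an
annual-cycle Markov cohort model whose disease-free population is split
into exposure pools (healthy, obese, smoker, obese+smoker) that feed the
T2D pool at pool-specific incidence rates, with T2D-related and other
death as competing absorbing states. It is aimed at epidemiologists and
health planners who have two cross-sectional surveys, census-based
demographic projections, and little else.

The machinery, each piece exposed and tested on its own:

* **Barendregt mortality split** — all-cause mortality *m*, prevalence *P*
  and relative mortality *R* give
  `m_nd = m / (1 + P(R−1))`, `m_d = R·m_nd`, preserving
  `P·m_d + (1−P)·m_nd = m` exactly.
* **DisMod-style incidence back-calculation** — inverts the illness-death
  balance `dP/da = i(1−P) − P(1−P)(m_d − m_nd)` on band midpoints
  (disease-free entry at 25; forward differences; zero remission), with a
  1-year forward integrator as independent oracle.
* **Attributable-incidence partition** — `i_h = i / Σ s_k r_k`,
  `i_k = r_k i_h`, so pool composition drift (rising obesity) raises total
  incidence.
* **Geometric trend fitting and capping** — per-stratum annual rates
  between survey anchors; obesity capped by a flat per-sex ceiling
  calibrated to target 2027 totals.
* **Policy scenarios** — phased relative reductions of risk-factor
  prevalence (e.g. −20% over 10 years).
* **Analysis of extremes** — joint min/max parameter runs bracketing the
  projection.
* **Synthetic-data generator** — two-anchor studies with known truth and
  binomial survey noise, for end-to-end testing.

The Tunisian 1997–2027 study ships as the packaged fixture: the 1997 and
2005 survey tables transcribed cell-for-cell, census-based demographic
anchors, and documented placeholder files (flagged `source: assumption`)
for the unpublished mortality and relative-risk inputs.

## Worked example

```r
library(t2dmarkov)

inp  <- tunisia_inputs()
base <- run_model(build_model_spec(inp))
scen <- run_model(build_model_spec(inp, scenarios = tunisia_scenarios()))

summary_tables(base, c(2005, 2015, 2027))
#>   year men_pct women_pct total_pct t2d_count_thousand live_thousand
#> 1 2005    14.1      13.8      13.9            740.459      5310.849
#> 2 2015    18.3      16.3      17.3           1131.391      6538.106
#> 3 2027    22.8      20.6      21.6           1724.503      7972.250

scenario_impact(base, scen) |> subset(year == 2027)
#>    year   sex prev_diff_pp persons_averted rel_reduction
#> 91 2027   men    0.5110854        19.52871    0.02240403
#> 92 2027 women    0.7533129        31.14904    0.03652379
#> 93 2027 total    0.6369412        50.67775    0.02938687
```

Reading: from the 1997 survey baseline (12.0% crude), the model hindcasts
13.9% overall T2D prevalence in 2005 (the 2005 survey's crude aggregate is
15.1%; women agree within 1 point, men less well), and projects 21.6% —
1.72 million people — by 2027 under continued, capped risk-factor trends.
The combined national tobacco and obesity strategies avert about 51
thousand cases by 2027: modest, because interventions act on future
incidence only and cannot shrink the existing caseload under the model's
non-reversibility contract. `extremes(inp)` brackets the 2027 projection
at roughly 20.6–22.8% under ±25% parameter bounds, and
`analysis/06_extremes.R` shows that the level of the back-calculated
incidence — the one genuinely unpublished ingredient of the original
study — is what separates these figures from the published 26.6%.

## The analysis pipeline

Numbered drivers under `analysis/` rebuild the study end to end, each
writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_inputs.R` | fixture overview; crude vs printed survey totals |
| `02_trends.R` | fitted trend rates, caps, 2027 risk-factor levels |
| `03_hindcast_validation.R` | 1997→2005 hindcast vs the 2005 survey |
| `04_forecast.R` | baseline projection to 2027 |
| `05_scenarios.R` | national-strategy scenario impact |
| `06_extremes.R` | extremes envelope and gap quantification |

Run them from the repository root, e.g. `Rscript analysis/04_forecast.R`.

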