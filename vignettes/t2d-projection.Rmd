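---
title: "Projecting type 2 diabetes prevalence with a multi-state Markov cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting type 2 diabetes prevalence with a multi-state Markov cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dmarkov)
```

## The model

`t2dmarkov` projects type 2 diabetes (T2D) prevalence in a population by
advancing age/sex-stratified counts through seven mutually exclusive
compartments in annual cycles:

* four disease-free exposure pools — *healthy* (non-obese non-smoker),
  *obese only*, *smoker only*, *obese and smoker*;
* the *T2D* pool;
* two absorbing death states — *T2D-related death* (the excess mortality of
  the diseased) and *other death* — treated as competing risks.

The contract is **non-reversibility**: people may move healthy → exposed →
T2D → death, never backwards. This mirrors populations where smoking
cessation and sustained weight loss are rare; where they are not, the model
overstates exposure and hence T2D.

Strata are two sexes crossed with 10-year age bands (default 25–34 … 75+,
closed-open intervals in whole years; the last band open-ended). The model
clock is whole calendar years; a state is labelled 1 January of its year.

### Incidence from prevalence: the illness-death inversion

Population-level T2D incidence is rarely observed directly. The package
back-calculates it from a cross-sectional survey using the illness-death
balance on age,

$$\frac{dP}{da} = i\,(1-P) - P\,(1-P)\,(m_d - m_{nd}),$$

where $P(a)$ is prevalence, $i$ incidence among the disease-free, and
$m_d$, $m_{nd}$ the mortality of the diseased and non-diseased. The
mortality split comes from the all-cause rate $m$ and the relative
mortality $R$ of the diseased (the Barendregt partition):

$$m_{nd} = \frac{m}{1 + P\,(R - 1)}, \qquad m_d = R\, m_{nd},$$

which preserves $P m_d + (1-P) m_{nd} = m$ exactly — a property-tested
identity.

`backcalculate_incidence()` solves the balance by finite differences
between consecutive band midpoints: the first band from the disease-free
entry condition $P(25) = 0$; interior bands from the forward difference to
the next midpoint with the balance evaluated at the segment's mean
prevalence (the centred evaluation keeps the inversion within 5% of a
1-year forward integration over 10-year segments); the open-ended last
band, which has no next midpoint, from the zero-gradient steady state.
Negative solutions — prevalence falling faster with age than excess
mortality explains — are floored at zero with a warning; the Tunisian men's
65–74 dip triggers this. `forward_prevalence()` integrates the same system
in 1-year steps and serves as the independent oracle in the tests; it lays
band rates on midpoint-delimited age segments, the same convention the
finite difference inverts. The boundary bands (entry-condition and
zero-gradient solves) are approximations outside the 5% bound, which is why
recovery tests assert interior bands.

### Exposure pools and attributable incidence

The population incidence $i$ is partitioned over the disease-free pools in
proportion to incidence relative risks $r_k$ (healthy $\equiv 1$):

$$i_{healthy} = \frac{i}{\sum_k s_k r_k}, \qquad i_k = r_k\, i_{healthy},$$

with $s_k$ the pool shares, so $\sum_k s_k i_k = i$ exactly. The partition
is computed at each anchor-survey year from the modelled shares and the
pool-specific rates are then held fixed until the next anchor
(`incidence_refresh = "anchors"`; `"annual"` re-derives everything from the
modelled prevalence each cycle). Holding pool rates fixed while the pool
composition drifts toward rising obesity is the mechanism by which
risk-factor trends raise total incidence — and the only channel through
which policy scenarios act.

### The annual cycle

`step_cohort()` applies, in documented order: (1) incidence per pool;
(2) cause-partitioned deaths (the excess $m_d - m_{nd}$ booked to T2D
death, the baseline to other death); (3) risk-factor drift — one-way flows
(healthy→obese, healthy→smoker, single→joint) rebalance the disease-free
marginals to next year's trajectories; a *declining* marginal (men's
smoking) triggers no reverse flow and is absorbed by entrant composition
and mortality, honouring non-reversibility; (4) ageing; (5) entrants: the
youngest band is topped up to next year's interpolated demography,
entering disease-free at the trajectory marginals. The order (incidence on
start-of-year pools) follows the annual-risk convention; the brute-force
oracle in the tests implements the same documented order independently and
agrees to $10^{-9}$.

Joint exposure at initialisation assumes independence of obesity and
smoking within the disease-free ($s_{ob\cap sm} = O \cdot S$) because no
joint table is surveyed; the engine accepts any non-negative pool split.

### Ageing: why single-year cohorts are the default

With fractional ageing (1/width of each band advances per year), sojourn
times are geometric: a non-trivial fraction reaches the open 75+ band far
too early, inflating it by ~40% over a 30-year horizon while depleting the
55–74 bands. The default `ageing_method = "single_year"` tracks one-year
age cohorts inside each band (uniform split at initialisation), so a
10-year band takes exactly 10 years to traverse, and modelled totals stay
within 2% of the demographic anchors. Fractional ageing remains available
and is what the toy oracle tests exercise.

### Trends, caps and scenarios

Risk-factor trends are constant *multiplicative* annual rates fitted per
stratum between the first and last anchor surveys,
$(p_{end}/p_{start})^{1/\Delta} - 1$: geometric change is the convention of
this model family, guarantees positivity, and composes across periods
(tested semigroup property). Trends are fitted per (sex, band), never on
totals — printed totals serve only as checks. Extrapolated obesity is
capped with a flat per-sex ceiling calibrated so the population-weighted
2027 total equals the published projections (27.0% men, 44.0% women by
default; the women's uncapped paths already aggregate to ~44%, so only the
men's cap binds, at ~34%). Capping encodes the observed "leveling off" of
obesity; a hard `min()` is the simplest ceiling consistent with that
evidence.

Scenarios multiply the (already capped) prevalence trajectories by a phased
factor: 1 before the start year, linearly down to $1 - \text{reduction}$
over the stated duration, constant after. Linear phase-in is the
conventional reading of "reduce by 20% in 10 years"; `immediate` is
available. Effects propagate only through incidence, so a scenario cannot
shrink the existing caseload — a structural consequence of
non-reversibility worth remembering when comparing with headline claims.

### Analysis of extremes

`extremes()` reruns the model with all flagged parameters jointly at the
orientation that minimises/maximises prevalence: trend rates (on the
magnitude: faster growth and slower decline for the maximum), caps and
incidence relative risks, all ±25% by default. Two sign conventions are
fixed by construction, not searched:

* perturbations apply only *beyond* the last anchor year — the 1997–2005
  path is surveyed data, and pivoting a fitted rate around its reference
  would move the observed window the wrong way;
* the mortality relative risk is **not** varied: raising it increases the
  back-calculated inflow early but the T2D death outflow later, a
  non-monotone net effect (~0.1 pp) that no single orientation brackets.

With these conventions min ≤ central ≤ max holds for every year and
stratum (property-tested).

### Mortality inputs

Age/sex all-cause mortality is not published with the survey tables, so the
fixture ships a Gompertz-like placeholder (flagged `source: assumption`)
giving 1997 crude 25+ death rates of ~10/1000 (men) and ~8/1000 (women),
plus a secular improvement of −1.5%/yr — the standard demographic reading
of Tunisia's rising life expectancy, and necessary for the cohort dynamics
to match the census-based 2027 anchors. The relative-mortality schedule
declines from 3.0 at 25–34 to 1.4 at 75+; incidence relative risks default
to 3.0 (obesity), 1.4 (smoking), multiplicative jointly. All are
configurable and bounded for the extremes analysis.

## The Tunisian study

```{r fixture}
inp <- tunisia_inputs()
run <- suppressWarnings(run_model(build_model_spec(inp)))
summary_tables(run, c(2005, 2015, 2027))
```

The packaged fixture transcribes the published 1997/2005 survey tables
cell-for-cell (one known internal inconsistency — the 2005 women's 25–34
smoking cell — is carried as printed and documented in the file header).
A noteworthy arithmetic fact, surfaced by `analysis/01_inputs.R`: the crude
population-weighted aggregate of the printed 1997 T2D cells is 12.0% and of
the 2005 cells 15.1%, matching the published *model* baselines, while the
printed totals rows (13.1%/15.2%) are survey-weighted; the engine consumes
the cells as printed.

Running `analysis/03_hindcast_validation.R` through
`analysis/06_extremes.R` reproduces the package's own results: a 2005
hindcast of about 13.9% overall (women within 1 point of the published
estimate), a 2027 baseline near 21.6% with a ±25% extremes envelope of
roughly 20.6–22.8%, and a 0.6 pp scenario reduction. These sit below the
published projections; the extremes machinery localises the discrepancy:
a single multiplier of ~1.2–1.3 on the back-calculated incidence level
reproduces both the published 2005 and 2027 figures, whereas the mortality
table (×1.5) and the ±25% parameter extremes move the 2027 projection by
about one point. The unpublished incidence procedure — steady-state
inversion of a single cross-section is only one reading, and the strong
secular rise between the two surveys implies a higher cohort incidence —
is therefore the binding unknown, not the mortality or relative-risk
assumptions.

## The synthetic-data generator

`generate_synthetic()` builds a complete two-anchor study with known truth:
steady-state first-anchor prevalence from `forward_prevalence()`, a
forward engine run to the second anchor, geometric demography closed except
for 25-year-old entrants, and optional binomial survey noise with a stated
effective sample size per stratum (defaults in the few-thousands, like the
real surveys). It emulates the data *structure* — two cross-sections with
multiplicative risk-factor drift — not survey design effects, clustering,
non-response or diagnostic-criterion changes; passing recovery tests
therefore demonstrate internal consistency of the pipeline, not robustness
to real survey artefacts. Generation is bit-reproducible under a seed.
Noise-free bundles recover trend rates to numerical precision and interior
incidence within the 5% discretisation bound; recovery error shrinks
monotonically with effective sample size.

## Numerical choices and degenerate inputs

* Proportions live on [0, 1] internally; CSV files carry percentages as
  surveys print them (UTF-8, comma-separated, dot decimal).
* Rates are treated as annual risks; flows are clipped so no pool goes
  negative, and person conservation (live + cumulative dead = initial +
  entrants) holds to $10^{-9}$ relative and is asserted in the tests.
* Zero-prevalence strata would make geometric rate fitting undefined; an
  additive floor (`zero_floor`, off by default) is provided. None occur in
  the fixture.
* A demographic target below modelled survivors floors entrants at zero
  with a warning (closing years of the Tunisian window trigger this
  benignly).
* Demography between anchors is geometric per stratum; against sparse
  anchors (2005 → 2027) this undershoots a decelerating growth path
  mid-period by up to ~4%, which is the main reason modelled totals are
  compared with the anchors, not the interpolation, at the 2% tolerance.
* Problem sizes: the full Tunisian run is 30 annual cycles over 12 strata
  (61 age rows internally) and completes in well under a second; the test
  suite's simulations are sized to run in seconds.

## Known limitations

* Steady-state incidence inversion of a single cross-section understates
  incidence when prevalence is rising secularly — quantified above; a
  two-survey (age–period) inversion would be the natural extension.
* Diagnosed vs undiagnosed T2D, remission, diagnosis lag, complications and
  costs are out of scope; relative risks are held constant over the
  horizon.
* The exposure-pool structure carries only obesity and smoking; other
  determinants (diet, activity, genetics) enter implicitly through the
  baseline incidence.
* Scenario effects act on future incidence only, so near-term caseload
  responses are structurally modest under non-reversibility.
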