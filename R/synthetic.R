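#' Synthetic study inputs with known ground truth
#'
#' Generates a complete two-anchor [study_inputs()] emulating the structure
#' of the Tunisian data, from a known truth: per-stratum T2D incidence, a
#' mortality schedule, relative risks, multiplicative risk-factor trends and
#' geometric demographic growth. The first anchor's prevalence profile is
#' the steady-state of the illness-death process ([forward_prevalence()]);
#' the second anchor is produced by running the Markov engine forward, so
#' every pipeline stage can be tested against the truth. Optional binomial
#' survey noise with a stated effective sample size per stratum mimics
#' survey sampling error.
#'
#' @param seed integer; regeneration with the same seed is bit-identical.
#' @param config a [synth_config()].
#' @return a `truth_bundle`: `seed`, `config`, `truth` (incidence table,
#'   trend rate matrices, parameters, exact anchor prevalences) and
#'   `inputs` (the generated, possibly noisy, [study_inputs()]).
#' @export
generate_synthetic <- function(seed, config = synth_config()) {
  set.seed(seed)
  cf <- config
  bl <- cf$bands
  mk <- function(m, kind, units = "") {
    rownames(m) <- bl; colnames(m) <- SEXES
    strat_table(m, kind, units)
  }
  mortality <- mk(cf$mortality, "rate", "per person-year")
  incidence <- mk(cf$incidence, "rate", "per disease-free person-year")
  pars <- cf$parameters
  prev0 <- forward_prevalence(incidence, mortality, pars$rr_mortality)
  if (any(prev0$values >= 1)) stop("infeasible config: prevalence reaches 1")
  a1 <- cf$anchor_years[1]; a2 <- cf$anchor_years[2]
  pop_at <- function(year) {
    mk(cf$base_pop * (1 + cf$pop_growth)^(year - a1), "count", "thousand")
  }
  demog <- lapply(c(cf$anchor_years, cf$horizon), pop_at)
  names(demog) <- c(cf$anchor_years, cf$horizon)
  ob0 <- mk(cf$obesity0, "proportion")
  sm0 <- mk(cf$smoking0, "proportion")
  snap1 <- survey_snapshot(a1, pop_at(a1), prev0, ob0, sm0)
  inputs1 <- study_inputs(list(snap1), demog, mortality, cf$horizon, pars)
  tspecs <- list(
    obesity = trend_spec("obesity", cf$trend_obesity, a1, ob0),
    smoking = trend_spec("smoking", cf$trend_smoking, a1, sm0))
  spec <- build_model_spec(inputs1, trend_specs = tspecs, start = a1)
  run <- suppressWarnings(run_model(spec, a1, a2))
  prev2 <- t2d_prevalence(run$states[[as.character(a2)]])
  ob2 <- mk(trajectory_at(spec$trajectories$obesity, a2), "proportion")
  sm2 <- mk(trajectory_at(spec$trajectories$smoking, a2), "proportion")
  noisy <- function(tab) {
    if (!is.finite(cf$effective_n)) return(tab)
    v <- tab$values
    v[] <- stats::rbinom(length(v), cf$effective_n, pmin(pmax(v, 0), 1)) /
      cf$effective_n
    strat_table(v, "proportion")
  }
  snap1n <- survey_snapshot(a1, pop_at(a1), noisy(prev0), noisy(ob0),
                            noisy(sm0))
  snap2n <- survey_snapshot(a2, pop_at(a2), noisy(prev2), noisy(ob2),
                            noisy(sm2))
  inputs <- study_inputs(list(snap1n, snap2n), demog, mortality, cf$horizon,
                         pars)
  structure(list(seed = seed, config = cf,
                 truth = list(incidence = incidence,
                              trend_obesity = cf$trend_obesity,
                              trend_smoking = cf$trend_smoking,
                              parameters = pars,
                              prev_anchor1 = prev0, prev_anchor2 = prev2),
                 inputs = inputs),
            class = "truth_bundle")
}

#' @rdname generate_synthetic
#' @param bands band labels.
#' @param anchor_years two survey years.
#' @param horizon horizon year.
#' @param base_pop,pop_growth band x sex population (thousands) at the first
#'   anchor and its geometric annual growth.
#' @param incidence,mortality band x sex truth rate matrices.
#' @param obesity0,smoking0 band x sex prevalences at the first anchor.
#' @param trend_obesity,trend_smoking band x sex annual multiplicative rates.
#' @param parameters a [model_parameters()].
#' @param effective_n binomial survey effective sample size per stratum;
#'   `Inf` for noise-free anchors. The Tunisian surveys sampled roughly
#'   3,600-8,000 adults, so finite defaults of a few thousand are realistic.
#' @export
synth_config <- function(bands = default_age_bands(),
                         anchor_years = c(1997, 2005), horizon = 2027,
                         base_pop = cbind(men = c(700, 550, 320, 260, 175, 90),
                                          women = c(750, 545, 330, 265, 200, 85)),
                         pop_growth = 0.02,
                         incidence = cbind(men = c(.004, .008, .012, .010, .008, .006),
                                           women = c(.003, .007, .011, .012, .009, .006)),
                         mortality = cbind(men = c(.0018, .0025, .0055, .013, .032, .095),
                                           women = c(.0010, .0016, .0035, .0085, .024, .085)),
                         obesity0 = cbind(men = c(.05, .11, .09, .08, .08, .10),
                                          women = c(.17, .28, .38, .32, .26, .16)),
                         smoking0 = cbind(men = c(.55, .50, .43, .33, .33, .33),
                                          women = c(.01, .02, .02, .02, .015, .01)),
                         trend_obesity = 0.06, trend_smoking = 0.02,
                         parameters = model_parameters(
                           mortality_improvement = 0),
                         effective_n = Inf) {
  n <- length(bands)
  as_mat <- function(x) {
    if (length(x) == 1) x <- matrix(x, n, 2) else x <- as.matrix(x)
    rownames(x) <- bands; colnames(x) <- SEXES
    x
  }
  list(bands = bands, anchor_years = anchor_years, horizon = horizon,
       base_pop = as_mat(base_pop), pop_growth = pop_growth,
       incidence = as_mat(incidence), mortality = as_mat(mortality),
       obesity0 = as_mat(obesity0), smoking0 = as_mat(smoking0),
       trend_obesity = as_mat(trend_obesity),
       trend_smoking = as_mat(trend_smoking),
       parameters = parameters, effective_n = effective_n)
}

#' Parameter-recovery experiment
#'
#' Runs the estimation stages on a generated bundle and reports relative
#' errors against the truth: [fit_trends()] between the two anchors versus
#' the true annual rates, and [backcalculate_incidence()] at the first
#' anchor versus the true incidence. On noise-free bundles trend rates are
#' recovered to numerical precision and incidence to within the
#' discretisation bound of the band-midpoint solver.
#'
#' @param bundle a `truth_bundle` from [generate_synthetic()].
#' @return list with matrices `trend_rel_err` (obesity & smoking stacked)
#'   and `incidence_rel_err`, plus the fitted objects.
#' @export
recovery_experiment <- function(bundle) {
  fitted <- fit_trends(bundle$inputs, obesity_targets = NULL)
  rel <- function(est, true) abs(est - true) / pmax(abs(true), 1e-12)
  trend_err <- rbind(
    obesity = rel(fitted$obesity$annual_rate, bundle$config$trend_obesity),
    smoking = rel(fitted$smoking$annual_rate, bundle$config$trend_smoking))
  snap1 <- bundle$inputs$anchor_surveys[[1]]
  inc <- suppressWarnings(backcalculate_incidence(
    snap1$t2d, bundle$inputs$mortality,
    bundle$inputs$parameters$rr_mortality))
  inc_err <- rel(inc$values, bundle$truth$incidence$values)
  list(trend_rel_err = trend_err, incidence_rel_err = inc_err,
       fitted_trends = fitted, fitted_incidence = inc)
}
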