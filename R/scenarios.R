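#' Policy-scenario specification
#'
#' A phased relative reduction of one risk factor's prevalence: nothing
#' before `start_year`, a linear (or immediate) phase-in to
#' `1 - relative_reduction` over `duration` years, held constant after.
#' The Tunisian national strategies are the defaults of
#' [tunisia_scenarios()]: smoking -20% over 10 years from 2009, obesity
#' -20% over 10 years from 2013.
#'
#' @param factor `"obesity"` or `"smoking"`.
#' @param relative_reduction proportion in `[0, 1]` (0.20 = minus 20%).
#' @param start_year first year of the phase-in.
#' @param duration years to full effect (>= 1).
#' @param phase_in `"linear"` or `"immediate"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(factor, relative_reduction, start_year,
                          duration = 10, phase_in = c("linear", "immediate")) {
  phase_in <- match.arg(phase_in)
  stopifnot(factor %in% c("obesity", "smoking"),
            relative_reduction >= 0, relative_reduction <= 1, duration >= 1)
  structure(list(factor = factor,
                 relative_reduction = relative_reduction,
                 start_year = as.integer(start_year),
                 duration = as.integer(duration), phase_in = phase_in),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
tunisia_scenarios <- function() {
  list(scenario_spec("smoking", 0.20, 2009, 10),
       scenario_spec("obesity", 0.20, 2013, 10))
}

#' @rdname scenario_spec
#' @param spec a `scenario_spec`.
#' @param year calendar year.
#' @return `scenario_multiplier()`: the prevalence multiplier at `year`
#'   (1 before the start, `1 - relative_reduction` at and after full effect).
#' @export
scenario_multiplier <- function(spec, year) {
  if (year <= spec$start_year) return(1)
  if (spec$phase_in == "immediate") return(1 - spec$relative_reduction)
  f <- min((year - spec$start_year) / spec$duration, 1)
  1 - f * spec$relative_reduction
}

#' Apply policy scenarios to risk-factor trajectories
#'
#' Pointwise multiplies each stratum's (already capped) trajectory by the
#' scenario multiplier, re-clipping to `[0, 1]`. Multipliers for the same
#' factor compound.
#'
#' @param trajectories named list of trajectory arrays from [extrapolate()].
#' @param specs list of [scenario_spec()]s.
#' @return the modified trajectory list.
#' @export
apply_scenarios <- function(trajectories, specs) {
  for (sc in specs) {
    if (!sc$factor %in% names(trajectories)) {
      stop("unknown factor in scenario: ", sc$factor)
    }
    traj <- trajectories[[sc$factor]]
    years <- as.integer(dimnames(traj)[[3]])
    for (k in seq_along(years)) {
      traj[, , k] <- pmin(pmax(traj[, , k] *
                                 scenario_multiplier(sc, years[k]), 0), 1)
    }
    trajectories[[sc$factor]] <- traj
  }
  trajectories
}

#' Impact of a scenario run versus the baseline
#'
#' Per year and sex: prevalence difference (percentage points, baseline
#' minus scenario), persons averted (baseline minus scenario T2D counts) and
#' the relative caseload reduction.
#'
#' @param baseline,scenario two [run_model()] results over identical years.
#' @return data.frame of class `impact_report`.
#' @export
scenario_impact <- function(baseline, scenario) {
  b <- baseline$summary; s <- scenario$summary
  if (!identical(b[c("year", "sex")], s[c("year", "sex")])) {
    stop("scenario_impact: mismatched runs")
  }
  out <- data.frame(
    year = b$year, sex = b$sex,
    prev_diff_pp = 100 * (b$prevalence - s$prevalence),
    persons_averted = b$t2d - s$t2d,
    rel_reduction = ifelse(b$t2d > 0, (b$t2d - s$t2d) / b$t2d, 0))
  class(out) <- c("impact_report", class(out))
  out
}

# Scale a fitted trend-spec list toward min/max prevalence. Rates are scaled
# multiplicatively on their magnitude (a +25% "max" makes growth faster and
# decline slower); caps are scaled directly and clipped to (0, 1].
perturb_trends <- function(trend_specs, factor_scale) {
  lapply(trend_specs, function(ts) {
    r <- ts$annual_rate
    r <- ifelse(r >= 0, r * factor_scale, r / factor_scale)
    cap <- ts$cap
    if (!is.null(cap)) cap <- pmin(pmax(cap * factor_scale, 1e-9), 1)
    trend_spec(ts$factor, r, ts$reference_year, ts$reference_level, cap)
  })
}

# Uncertainty applies to the extrapolated continuation, not the observed
# 1997-2005 window: use the central path up to each trend's reference year
# (the last anchor) and the perturbed path beyond it.
splice_trajectories <- function(central, perturbed, specs) {
  out <- central
  for (f in names(central)) {
    yrs <- as.integer(dimnames(central[[f]])[[3]])
    after <- yrs > specs[[f]]$reference_year
    out[[f]][, , after] <- perturbed[[f]][, , after]
  }
  out
}

#' Analysis of extremes
#'
#' Deterministic sensitivity analysis: rebuild and rerun the model with all
#' flagged parameters (incidence relative risks, trend rates and caps)
#' jointly at the bound orientation that minimises, respectively maximises,
#' projected T2D prevalence. Orientations are fixed sign conventions,
#' documented in the package vignette, not searched per run: prevalence is
#' increasing in trend rates, caps and incidence relative risks in every
#' simulated year. The mortality relative risk is not varied: its effect is
#' non-monotone over the horizon (raising it increases the back-calculated
#' inflow early but the T2D outflow later) and an order of magnitude smaller
#' than the other parameters, so no single orientation preserves the
#' bracketing guarantee.
#'
#' @param inputs a [study_inputs()].
#' @param scenarios optional scenario list applied to all three runs.
#' @param bounds_rel relative bound half-width; defaults to the parameter
#'   bundle's (0.25). `0` gives three identical runs.
#' @param obesity_targets,incidence_refresh passed to [build_model_spec()].
#' @return list of three `model_run`s: `min_run`, `central`, `max_run`.
#' @export
extremes <- function(inputs, scenarios = NULL,
                     bounds_rel = inputs$parameters$bounds_rel,
                     obesity_targets = c(men = 0.270, women = 0.440),
                     incidence_refresh = "anchors") {
  stopifnot(bounds_rel >= 0, bounds_rel < 1)
  central_pars <- inputs$parameters
  start <- anchor_years(inputs)[1]
  base <- fit_trends(inputs, obesity_targets = obesity_targets)
  base_traj <- lapply(base, extrapolate, start = start,
                      horizon = inputs$horizon_year)
  one_run <- function(scale) {
    if (scale == 1) {
      spec <- build_model_spec(inputs, scenarios = scenarios,
                               trend_specs = base,
                               obesity_targets = obesity_targets,
                               incidence_refresh = incidence_refresh)
    } else {
      pars <- central_pars
      pars$rr_incidence[POOLS[-1]] <-
        pmax(pars$rr_incidence[POOLS[-1]] * scale, 1)
      pert <- perturb_trends(base, scale)
      pert_traj <- lapply(pert, extrapolate, start = start,
                          horizon = inputs$horizon_year)
      spec <- build_model_spec(inputs, scenarios = scenarios,
                               parameters = pars, trend_specs = pert,
                               obesity_targets = obesity_targets,
                               incidence_refresh = incidence_refresh,
                               trajectories = splice_trajectories(
                                 base_traj, pert_traj, base))
    }
    suppressWarnings(run_model(spec))
  }
  list(min_run = one_run(1 - bounds_rel),
       central = one_run(1),
       max_run = one_run(1 + bounds_rel))
}
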