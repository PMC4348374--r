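#' Geometric annual change rate between two survey anchors
#'
#' Constant multiplicative year-on-year change: `(p_end / p_start)^(1/span)
#' - 1`. Geometric (rather than arithmetic) change is the convention of this
#' model family and guarantees positivity of extrapolated prevalences.
#'
#' @param p_start,p_end prevalence (proportions) at the two anchors;
#'   vectorised.
#' @param span years between the anchors (>= 1).
#' @return annual multiplicative rate (e.g. 0.064 for +6.4%/year).
#' @export
annual_change_rate <- function(p_start, p_end, span) {
  stopifnot(span >= 1, all(p_end >= 0))
  if (any(p_start <= 0 & p_end > 0)) {
    stop("undefined rate: zero start prevalence with positive end; ",
         "apply an additive floor before fitting")
  }
  ifelse(p_start == 0, 0, (p_end / p_start)^(1 / span) - 1)
}

#' Risk-factor trend specification
#'
#' Per-stratum multiplicative annual rates anchored at a reference year, with
#' an optional hard prevalence ceiling (the "leveling-off" cap).
#'
#' @param factor `"obesity"` or `"smoking"`.
#' @param annual_rate numeric matrix (band x sex) of annual rates, each > -1.
#' @param reference_year calendar year of `reference_level`.
#' @param reference_level proportion `strat_table` at the reference year.
#' @param cap `NULL`, or a numeric matrix / single number in (0, 1] giving
#'   the per-stratum ceiling.
#' @return object of class `trend_spec`.
#' @export
trend_spec <- function(factor, annual_rate, reference_year, reference_level,
                       cap = NULL) {
  stopifnot(factor %in% c("obesity", "smoking"),
            inherits(reference_level, "strat_table"),
            all(annual_rate > -1))
  ref <- reference_level$values
  if (!is.matrix(annual_rate)) {
    annual_rate <- matrix(annual_rate, nrow(ref), ncol(ref),
                          dimnames = dimnames(ref))
  }
  if (!is.null(cap)) {
    if (length(cap) == 1) {
      cap <- matrix(cap, nrow(ref), ncol(ref), dimnames = dimnames(ref))
    }
    stopifnot(all(cap > 0), all(cap <= 1))
  }
  structure(list(factor = factor, annual_rate = annual_rate,
                 reference_year = as.integer(reference_year),
                 reference_level = reference_level, cap = cap),
            class = "trend_spec")
}

#' Evaluate / extrapolate a trend
#'
#' `trend_level()` returns `min(cap, ref * (1 + rate)^(year - ref_year))`
#' clipped to `[0, 1]`; `extrapolate()` evaluates it over a span of years,
#' returning a band x sex x year array (a risk-factor trajectory).
#'
#' @param spec a [trend_spec()].
#' @param year calendar year (scalar).
#' @return `trend_level()`: band x sex matrix of prevalences.
#' @export
trend_level <- function(spec, year) {
  lev <- spec$reference_level$values *
    (1 + spec$annual_rate)^(year - spec$reference_year)
  if (!is.null(spec$cap)) lev <- pmin(lev, spec$cap)
  pmin(pmax(lev, 0), 1)
}

#' @rdname trend_level
#' @param start,horizon first and last calendar year of the trajectory.
#' @export
extrapolate <- function(spec, start, horizon) {
  stopifnot(start <= horizon)
  years <- start:horizon
  ref <- spec$reference_level$values
  traj <- array(NA_real_, c(nrow(ref), ncol(ref), length(years)),
                dimnames = c(dimnames(ref), list(years)))
  for (k in seq_along(years)) traj[, , k] <- trend_level(spec, years[k])
  attr(traj, "factor") <- spec$factor
  traj
}

#' @rdname trend_level
#' @param traj a trajectory array from [extrapolate()].
#' @export
trajectory_at <- function(traj, year) {
  k <- match(as.character(year), dimnames(traj)[[3]])
  if (is.na(k)) stop("trajectory does not cover year ", year)
  m <- traj[, , k, drop = FALSE]
  dim(m) <- dim(traj)[1:2]
  dimnames(m) <- dimnames(traj)[1:2]
  m
}

#' Calibrate a flat per-sex prevalence ceiling to a target total
#'
#' Solves for the single ceiling `c` such that the population-weighted total
#' of `pmin(path, c)` equals `target` at the calibration year. If the
#' uncapped total is already at or below the target, no cap is needed and
#' `NULL` is returned.
#'
#' @param path numeric vector of uncapped per-band prevalences at the
#'   calibration year (already clipped to `[0, 1]`).
#' @param weights population weights for the same bands.
#' @param target target weighted total (proportion).
#' @return a single ceiling in (0, 1], or `NULL`.
#' @export
calibrate_cap <- function(path, weights, target) {
  stopifnot(length(path) == length(weights), target > 0, target <= 1)
  w <- weights / sum(weights)
  if (sum(w * path) <= target) return(NULL)
  f <- function(cc) sum(w * pmin(path, cc)) - target
  stats::uniroot(f, lower = 1e-9, upper = 1, tol = 1e-12)$root
}

#' Fit risk-factor trends from the anchor surveys
#'
#' Per factor and (sex, age band) stratum, the geometric annual rate between
#' the first and last anchor surveys; the reference is the last anchor.
#' Obesity is capped with a flat per-sex ceiling calibrated so the
#' population-weighted obesity total at `cap_year` (weighted by the
#' interpolated demography) equals `obesity_targets`; smoking is uncapped.
#' Strata with zero prevalence at the first anchor receive `zero_floor`
#' before rate fitting (off when 0; no such strata occur in the packaged
#' fixture).
#'
#' @param inputs a [study_inputs()] with at least two anchors.
#' @param obesity_targets named proportions `c(men = , women = )` for the
#'   capped obesity totals at `cap_year`, or `NULL` for no capping.
#' @param cap_year calibration year for the cap (default: the horizon).
#' @param zero_floor additive floor applied to zero start prevalences.
#' @return named list of [trend_spec()]s (`obesity`, `smoking`).
#' @export
fit_trends <- function(inputs,
                       obesity_targets = c(men = 0.270, women = 0.440),
                       cap_year = inputs$horizon_year, zero_floor = 0) {
  if (length(inputs$anchor_surveys) < 2) {
    stop("fit_trends needs >= 2 anchor surveys; supply an explicit ",
         "trend_spec instead")
  }
  first <- inputs$anchor_surveys[[1]]
  last <- inputs$anchor_surveys[[length(inputs$anchor_surveys)]]
  span <- last$year - first$year
  specs <- list()
  for (factor in c("obesity", "smoking")) {
    p0 <- first[[factor]]$values
    p1 <- last[[factor]]$values
    if (zero_floor > 0) p0 <- pmax(p0, zero_floor)
    rate <- annual_change_rate(p0, p1, span)
    cap <- NULL
    if (factor == "obesity" && !is.null(obesity_targets)) {
      spec0 <- trend_spec(factor, rate, last$year, last[[factor]])
      lev <- trend_level(spec0, cap_year)
      wpop <- interpolate_demography(inputs, cap_year)$values
      cap <- matrix(NA_real_, nrow(lev), ncol(lev), dimnames = dimnames(lev))
      capped_any <- FALSE
      for (sex in SEXES) {
        cc <- calibrate_cap(lev[, sex], wpop[, sex], obesity_targets[[sex]])
        cap[, sex] <- if (is.null(cc)) 1 else { capped_any <- TRUE; cc }
      }
      if (!capped_any) cap <- NULL
    }
    specs[[factor]] <- trend_spec(factor, rate, last$year, last[[factor]],
                                  cap)
  }
  specs
}
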