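#' Model specification
#'
#' Bundles everything one simulation needs: the study inputs, the per-factor
#' risk-factor trajectories, the per-anchor disease-rate regimes and options.
#' `build_model_spec()` is the convenience constructor that fits trends,
#' extrapolates trajectories over `start..horizon`, applies any policy
#' scenarios and back-calculates the rate regimes.
#'
#' @param inputs a [study_inputs()].
#' @param scenarios optional list of [scenario_spec()]s applied to the
#'   trajectories.
#' @param obesity_targets passed to [fit_trends()] (cap calibration);
#'   `NULL` disables capping.
#' @param parameters a [model_parameters()]; defaults to the one in `inputs`.
#' @param incidence_refresh `"anchors"` (population incidence back-calculated
#'   at each anchor survey and pool rates re-partitioned there) or `"annual"`
#'   (re-derived from modelled prevalence every cycle).
#' @param ageing_method `"single_year"` (explicit one-year age cohorts inside
#'   each band; sojourn time in a 10-year band is exactly 10 years) or
#'   `"fractional"` (1/width of each band advances per cycle; geometric
#'   sojourn). Single-year is the default because fractional ageing smears
#'   cohorts into the open-ended band over a 30-year horizon and breaks
#'   demographic fidelity.
#' @param start first simulated year; must be an anchor-survey year.
#' @param trend_specs optionally, precomputed [fit_trends()] output (so
#'   extremes runs can perturb rates without refitting).
#' @param trajectories optionally, precomputed trajectory arrays (bypassing
#'   extrapolation of `trend_specs`); scenarios still apply on top.
#' @return object of class `model_spec`.
#' @export
build_model_spec <- function(inputs, scenarios = NULL,
                             obesity_targets = c(men = 0.270, women = 0.440),
                             parameters = inputs$parameters,
                             incidence_refresh = c("anchors", "annual"),
                             ageing_method = c("single_year", "fractional"),
                             start = anchor_years(inputs)[1],
                             trend_specs = NULL, trajectories = NULL) {
  incidence_refresh <- match.arg(incidence_refresh)
  ageing_method <- match.arg(ageing_method)
  if (is.null(trend_specs)) {
    trend_specs <- fit_trends(inputs, obesity_targets = obesity_targets)
  }
  horizon <- inputs$horizon_year
  if (is.null(trajectories)) {
    trajectories <- lapply(trend_specs, extrapolate, start = start,
                           horizon = horizon)
  }
  if (!is.null(scenarios)) {
    trajectories <- apply_scenarios(trajectories, scenarios)
  }
  inputs$parameters <- parameters
  structure(list(inputs = inputs, trend_specs = trend_specs,
                 trajectories = trajectories,
                 rates = build_disease_rates(inputs, parameters),
                 parameters = parameters,
                 incidence_refresh = incidence_refresh,
                 ageing_method = ageing_method,
                 start = as.integer(start)),
            class = "model_spec")
}

new_cohort_state <- function(year, counts, band_index) {
  structure(list(year = as.integer(year), counts = counts,
                 band_index = band_index),
            class = "cohort_state")
}

# Row layout of the state array: one row per single-year age (single_year)
# or one row per band (fractional). Returns the band index of every row.
state_layout <- function(bands, ageing_method) {
  if (ageing_method == "fractional") {
    list(labels = bands$label, band_index = seq_len(nrow(bands)),
         terminal_width = NA)
  } else {
    last_lower <- bands$lower[nrow(bands)]
    ages <- bands$lower[1]:(last_lower + 10)  # last row is terminal (85+)
    list(labels = as.character(ages),
         band_index = band_of_age(ages, bands), ages = ages)
  }
}

#' Initialize the cohort state at an anchor year
#'
#' Splits each stratum's population into the T2D pool (prevalence x
#' population) and four mutually exclusive disease-free pools from the
#' marginal obesity and smoking prevalences, assuming independence of the
#' two exposures within the disease-free (no joint table is available from
#' the surveys). Death pools start at zero. Under single-year ageing each
#' band's count is spread uniformly over its one-year ages.
#'
#' @param spec a [build_model_spec()].
#' @param year an anchor-survey year.
#' @return a `cohort_state`: year plus a row x sex x compartment count array
#'   (thousands), rows being ages or bands depending on the ageing method.
#' @export
initialize_cohort <- function(spec, year = spec$start) {
  snap <- NULL
  for (s in spec$inputs$anchor_surveys) if (s$year == year) snap <- s
  if (is.null(snap)) stop("initialize: ", year, " is not an anchor year")
  bands <- parse_age_bands(band_labels(snap$population))
  lay <- state_layout(bands, spec$ageing_method)
  bi <- lay$band_index
  attr(bi, "band_labels") <- bands$label
  nrows <- length(bi)
  counts <- array(0, c(nrows, 2, length(COMPARTMENTS)),
                  dimnames = list(lay$labels, SEXES, COMPARTMENTS))
  rows_per_band <- tabulate(bi, nbins = nrow(bands))
  pop_row <- snap$population$values[bi, ] / rows_per_band[bi]
  prev <- snap$t2d$values[bi, ]
  O <- snap$obesity$values[bi, ]
  S <- snap$smoking$values[bi, ]
  t2d <- prev * pop_row
  df <- pop_row - t2d
  counts[, , "t2d"] <- t2d
  counts[, , "healthy"] <- df * (1 - O) * (1 - S)
  counts[, , "obese"] <- df * O * (1 - S)
  counts[, , "smoker"] <- df * (1 - O) * S
  counts[, , "obese_smoker"] <- df * O * S
  new_cohort_state(year, counts, bi)
}

# Pool-specific annual incidence rates: partition each row's band-level
# population incidence across the row's current disease-free composition.
refresh_pool_rates <- function(counts, band_index, i_pop, rr_incidence) {
  nrows <- dim(counts)[1]
  rates <- array(0, c(nrows, 2, length(POOLS)),
                 dimnames = list(dimnames(counts)[[1]], SEXES, POOLS))
  for (sex in SEXES) {
    for (r in seq_len(nrows)) {
      pools <- counts[r, sex, POOLS]
      tot <- sum(pools)
      shares <- if (tot > 0) pools / tot else
        stats::setNames(rep(0.25, 4), POOLS)
      rates[r, sex, ] <- partition_incidence(
        i_pop$values[band_index[r], sex], shares, rr_incidence)
    }
  }
  rates
}

#' Advance the cohort one annual cycle
#'
#' Applies, in this documented order: (1) T2D incidence per pool (pool rates
#' held from the last refresh); (2) cause-partitioned deaths -- the T2D pool
#' dies at the diseased rate with the excess over the non-diseased rate
#' booked to `dead_t2d` and the baseline share to `dead_other`, disease-free
#' pools die at the non-diseased rate into `dead_other`; (3) risk-factor
#' drift -- one-way flows (healthy to obese/smoker, single-exposure to
#' obese+smoker) rebalance the disease-free marginals to next year's
#' trajectories, with required decreases absorbed by entrant composition
#' rather than reverse flows; (4) ageing; (5) new entrants fill the youngest
#' band to next year's interpolated demography, entering disease-free at the
#' trajectory marginals.
#'
#' @param state a `cohort_state`.
#' @param spec a [build_model_spec()].
#' @param pool_rates row x sex x pool incidence array from the last refresh.
#' @param regime rate regime (element of `spec$rates`) in force.
#' @return list with the advanced `state` and the cycle's `flows` (per sex:
#'   incident cases, deaths by cause, entrants, thousands).
#' @export
step_cohort <- function(state, spec, pool_rates, regime) {
  C <- state$counts
  bi <- state$band_index
  bands <- parse_age_bands(band_labels(spec$inputs$mortality))
  y <- state$year
  if (y >= spec$inputs$horizon_year) stop("step: horizon already reached")
  flows <- list()
  fac <- (1 - spec$parameters$mortality_improvement)^(y - regime$year)
  for (sex in SEXES) {
    m_nd <- regime$m_nondiseased$values[bi, sex] * fac
    m_d <- regime$m_diseased$values[bi, sex] * fac
    # (1) incidence
    new_cases <- vapply(POOLS, function(p) {
      pmin(C[, sex, p], C[, sex, p] * pool_rates[, sex, p])
    }, numeric(dim(C)[1]))
    if (is.null(dim(new_cases))) {
      new_cases <- matrix(new_cases, 1, dimnames = list(NULL, POOLS))
    }
    for (p in POOLS) C[, sex, p] <- C[, sex, p] - new_cases[, p]
    C[, sex, "t2d"] <- C[, sex, "t2d"] + rowSums(new_cases)
    # (2) deaths
    df_deaths <- 0
    for (p in POOLS) {
      d <- C[, sex, p] * m_nd
      C[, sex, p] <- C[, sex, p] - d
      df_deaths <- df_deaths + d
    }
    t2d_base <- C[, sex, "t2d"] * m_nd
    t2d_excess <- C[, sex, "t2d"] * (m_d - m_nd)
    C[, sex, "t2d"] <- C[, sex, "t2d"] - t2d_base - t2d_excess
    C[, sex, "dead_other"] <- C[, sex, "dead_other"] + df_deaths + t2d_base
    C[, sex, "dead_t2d"] <- C[, sex, "dead_t2d"] + t2d_excess
    flows[[sex]] <- c(incident = sum(new_cases),
                      deaths_t2d = sum(t2d_excess),
                      deaths_other = sum(df_deaths + t2d_base))
  }
  # (3) risk-factor drift toward next year's trajectory marginals
  O_t <- trajectory_at(spec$trajectories$obesity, y + 1)
  S_t <- trajectory_at(spec$trajectories$smoking, y + 1)
  for (sex in SEXES) {
    for (r in seq_along(bi)) {
      pools <- C[r, sex, POOLS]
      df <- sum(pools)
      if (df <= 0) next
      b <- bi[r]
      need_o <- O_t[b, sex] * df - (pools["obese"] + pools["obese_smoker"])
      non_ob <- pools["healthy"] + pools["smoker"]
      if (need_o > 0 && non_ob > 0) {
        f <- min(need_o / non_ob, 1)
        mh <- f * pools["healthy"]; ms <- f * pools["smoker"]
        pools["healthy"] <- pools["healthy"] - mh
        pools["obese"] <- pools["obese"] + mh
        pools["smoker"] <- pools["smoker"] - ms
        pools["obese_smoker"] <- pools["obese_smoker"] + ms
      }
      need_s <- S_t[b, sex] * df - (pools["smoker"] + pools["obese_smoker"])
      non_sm <- pools["healthy"] + pools["obese"]
      if (need_s > 0 && non_sm > 0) {
        f <- min(need_s / non_sm, 1)
        mh <- f * pools["healthy"]; mo <- f * pools["obese"]
        pools["healthy"] <- pools["healthy"] - mh
        pools["smoker"] <- pools["smoker"] + mh
        pools["obese"] <- pools["obese"] - mo
        pools["obese_smoker"] <- pools["obese_smoker"] + mo
      }
      C[r, sex, POOLS] <- pools
    }
  }
  # (4) ageing
  if (spec$ageing_method == "fractional") {
    frac <- ifelse(is.finite(bands$width), 1 / bands$width, 0)
    for (sex in SEXES) {
      for (comp in LIVE) {
        v <- C[, sex, comp]
        out <- v * frac
        v <- v - out
        if (length(v) > 1) v[-1] <- v[-1] + out[-length(out)]
        C[, sex, comp] <- v
      }
    }
  } else {
    n <- dim(C)[1]
    for (sex in SEXES) {
      for (comp in LIVE) {
        v <- C[, sex, comp]
        v <- c(0, v[-n] ) + c(rep(0, n - 1), v[n])  # shift; terminal keeps
        C[, sex, comp] <- v
      }
    }
  }
  # (5) entrants into the youngest band
  demo_next <- interpolate_demography(spec$inputs, y + 1)$values
  young <- which(bi == 1)
  for (sex in SEXES) {
    alive1 <- sum(C[young, sex, LIVE])
    e <- demo_next[1, sex] - alive1
    if (e < 0) {
      warning(sprintf("negative entrants floored at 0 for (%s) in %d", sex,
                      y + 1))
      e <- 0
    }
    O1 <- O_t[1, sex]; S1 <- S_t[1, sex]
    r1 <- young[1]
    C[r1, sex, "healthy"] <- C[r1, sex, "healthy"] + e * (1 - O1) * (1 - S1)
    C[r1, sex, "obese"] <- C[r1, sex, "obese"] + e * O1 * (1 - S1)
    C[r1, sex, "smoker"] <- C[r1, sex, "smoker"] + e * (1 - O1) * S1
    C[r1, sex, "obese_smoker"] <- C[r1, sex, "obese_smoker"] + e * O1 * S1
    flows[[sex]] <- c(flows[[sex]], entrants = e)
  }
  list(state = new_cohort_state(y + 1, C, bi), flows = flows)
}

#' Run the model from an anchor year to the horizon
#'
#' [initialize_cohort()] then repeated [step_cohort()], refreshing the
#' pool-specific incidence rates at anchor years (or every cycle under
#' `incidence_refresh = "annual"`, where the population incidence is also
#' re-back-calculated from the modelled prevalence).
#'
#' @param spec a [build_model_spec()].
#' @param start first year (anchor); defaults to the spec's start.
#' @param horizon last simulated year.
#' @return object of class `model_run`: `states` (one `cohort_state` per
#'   year), `summary` (data.frame: year, sex incl. `"total"`, live count,
#'   T2D count, prevalence, incident cases, deaths by cause, entrants) and
#'   bookkeeping used by the conservation check.
#' @export
run_model <- function(spec, start = spec$start,
                      horizon = spec$inputs$horizon_year) {
  state <- initialize_cohort(spec, start)
  anchors <- as.integer(names(spec$rates))
  states <- list()
  states[[as.character(start)]] <- state
  flow_rows <- list()
  pool_rates <- NULL
  regime <- NULL
  cum_entrants <- 0
  if (start < horizon) for (y in start:(horizon - 1)) {
    ra <- max(anchors[anchors <= y])
    if (spec$incidence_refresh == "annual") {
      prev_now <- t2d_prevalence(state)
      imp <- (1 - spec$parameters$mortality_improvement)^(y - min(anchors))
      mort <- strat_table(spec$inputs$mortality$values * imp, "rate")
      rrm <- spec$parameters$rr_mortality
      i_pop <- suppressWarnings(
        backcalculate_incidence(prev_now, mort, rrm))
      sp_nd <- mort$values * NA_real_; sp_d <- sp_nd
      for (sex in SEXES) {
        sp <- split_mortality(mort$values[, sex], prev_now$values[, sex],
                              rrm[band_labels(mort)])
        sp_nd[, sex] <- sp$m_nondiseased; sp_d[, sex] <- sp$m_diseased
      }
      regime <- list(i_pop = i_pop,
                     m_nondiseased = strat_table(sp_nd, "rate"),
                     m_diseased = strat_table(sp_d, "rate"), year = y)
      pool_rates <- refresh_pool_rates(state$counts, state$band_index,
                                       i_pop, spec$parameters$rr_incidence)
    } else if (y %in% anchors || is.null(pool_rates)) {
      regime <- spec$rates[[as.character(ra)]]
      pool_rates <- refresh_pool_rates(state$counts, state$band_index,
                                       regime$i_pop,
                                       spec$parameters$rr_incidence)
    }
    stepped <- step_cohort(state, spec, pool_rates, regime)
    state <- stepped$state
    states[[as.character(state$year)]] <- state
    for (sex in SEXES) {
      flow_rows[[length(flow_rows) + 1]] <-
        data.frame(year = y, sex = sex, t(stepped$flows[[sex]]))
      cum_entrants <- cum_entrants + stepped$flows[[sex]][["entrants"]]
    }
  }
  flows <- if (length(flow_rows)) do.call(rbind, flow_rows) else NULL
  run <- structure(list(states = states, spec = spec,
                        start = as.integer(start),
                        horizon = as.integer(horizon),
                        flows = flows, cum_entrants = cum_entrants),
                   class = "model_run")
  run$summary <- summarize_run(run)
  run
}

#' @rdname run_model
#' @param state a `cohort_state`.
#' @return `t2d_prevalence()`: per-band T2D prevalence `strat_table` of a
#'   state (rows aggregated to the model banding).
#' @export
t2d_prevalence <- function(state) {
  bc <- band_counts(state)
  live <- apply(bc[, , LIVE, drop = FALSE], c(1, 2), sum)
  p <- bc[, , "t2d"] / ifelse(live > 0, live, 1)
  strat_table(p, "proportion")
}

#' @rdname run_model
#' @return `band_counts()`: the state's counts aggregated to band x sex x
#'   compartment.
#' @export
band_counts <- function(state) {
  bi <- state$band_index
  nb <- max(bi)
  out <- array(0, c(nb, 2, length(COMPARTMENTS)),
               dimnames = list(NULL, SEXES, COMPARTMENTS))
  for (b in seq_len(nb)) {
    rows <- which(bi == b)
    out[b, , ] <- apply(state$counts[rows, , , drop = FALSE], c(2, 3), sum)
  }
  bl <- attr(bi, "band_labels")
  rownames(out) <- if (!is.null(bl)) bl else paste0("band", seq_len(nb))
  out
}

summarize_run <- function(run) {
  rows <- list()
  for (state in run$states) {
    live_rs <- apply(state$counts[, , LIVE, drop = FALSE], c(1, 2), sum)
    for (sex in c(SEXES, "total")) {
      cols <- if (sex == "total") SEXES else sex
      live <- sum(live_rs[, cols])
      t2d <- sum(state$counts[, cols, "t2d"])
      rows[[length(rows) + 1]] <- data.frame(
        year = state$year, sex = sex, live = live, t2d = t2d,
        prevalence = if (live > 0) t2d / live else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(run$flows)) {
    fl <- run$flows
    tot <- stats::aggregate(fl[c("incident", "deaths_t2d", "deaths_other",
                                 "entrants")],
                            by = fl["year"], FUN = sum)
    tot$sex <- "total"
    fl <- rbind(fl, tot[names(fl)])
    out <- merge(out, fl, by = c("year", "sex"), all.x = TRUE, sort = FALSE)
  }
  out[order(out$year, match(out$sex, c(SEXES, "total"))), ]
}

#' @rdname run_model
#' @param run a `model_run`.
#' @param year calendar year.
#' @param sex `"men"`, `"women"` or `"total"`.
#' @return `run_prevalence()`: the population-weighted T2D prevalence
#'   (proportion) of the modelled live population.
#' @export
run_prevalence <- function(run, year, sex = "total") {
  s <- run$summary
  v <- s$prevalence[s$year == year & s$sex == sex]
  if (!length(v)) stop("year ", year, " / sex ", sex, " not in run")
  v
}

#' @rdname run_model
#' @return `conservation_error()`: the relative error of
#'   live + cumulative dead versus initial population + cumulative entrants.
#' @export
conservation_error <- function(run) {
  first <- run$states[[1]]
  last <- run$states[[length(run$states)]]
  init <- sum(first$counts[, , LIVE])
  final <- sum(last$counts)  # live + cumulative dead
  abs(final - (init + run$cum_entrants)) / (init + run$cum_entrants)
}
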