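#' Epidemiological model parameters
#'
#' Relative mortality of T2D versus non-T2D by age band (the Verona-study
#' quantity), relative risks of T2D incidence for the exposure pools, and
#' per-parameter bounds for the analysis of extremes. The shipped defaults
#' are literature-informed assumptions (`source: assumption` in the fixture
#' files): an age-declining mortality ratio from about 3 in early adulthood
#' to about 1.4 at 75+, incidence relative risks of 3.0 for obesity and 1.4
#' for smoking with a multiplicative joint effect, and +/-25% bounds.
#'
#' @param rr_mortality named numeric vector of T2D relative mortality per age
#'   band (names = band labels).
#' @param rr_incidence named numeric vector with elements `obese`, `smoker`,
#'   `obese_smoker` (relative to the healthy pool).
#' @param bounds_rel relative half-width of the min/max bounds used by
#'   [extremes()] (0.25 means central x 0.75 and x 1.25).
#' @param mortality_improvement annual relative decline of all-cause
#'   mortality over calendar time (0.015 = minus 1.5% per year, a standard
#'   demographic-projection assumption consistent with Tunisia's rising life
#'   expectancy; the packaged mortality table is referenced at the first
#'   anchor year).
#' @param incidence_scale multiplier applied to the back-calculated
#'   population incidence (default 1). A diagnostic lever for quantifying
#'   how far an alternative incidence procedure (the steady-state inversion
#'   is only one possible reading of a cross-sectional survey) would move
#'   the projections; it is not varied by [extremes()].
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(rr_mortality = NULL,
                             rr_incidence = c(obese = 3.0, smoker = 1.4,
                                              obese_smoker = 3.0 * 1.4),
                             bounds_rel = 0.25,
                             mortality_improvement = 0.015,
                             incidence_scale = 1) {
  if (is.null(rr_mortality)) {
    rr_mortality <- c("25-34" = 3.0, "35-44" = 2.8, "45-54" = 2.3,
                      "55-64" = 1.9, "65-74" = 1.6, "75+" = 1.4)
  }
  stopifnot(all(rr_mortality > 0), bounds_rel >= 0, bounds_rel < 1)
  need <- c("obese", "smoker", "obese_smoker")
  if (!all(need %in% names(rr_incidence))) {
    stop("rr_incidence must name ", paste(need, collapse = ", "))
  }
  stopifnot(mortality_improvement >= 0, mortality_improvement < 1,
            incidence_scale > 0)
  structure(list(rr_mortality = rr_mortality,
                 rr_incidence = c(healthy = 1, rr_incidence[need]),
                 bounds_rel = bounds_rel,
                 mortality_improvement = mortality_improvement,
                 incidence_scale = incidence_scale),
            class = "model_parameters")
}

#' Partition all-cause mortality by disease status
#'
#' Barendregt-style split: given all-cause mortality `m_all`, disease
#' prevalence `prev` and relative mortality `rr`, the non-diseased rate is
#' `m_all / (1 + prev * (rr - 1))` and the diseased rate is `rr` times that,
#' so that `prev * m_d + (1 - prev) * m_nd == m_all` exactly.
#'
#' @param m_all all-cause mortality rate (per person-year); vectorised.
#' @param prev disease prevalence in `[0, 1)`.
#' @param rr relative mortality (> 0).
#' @return list with elements `m_nondiseased`, `m_diseased`.
#' @export
split_mortality <- function(m_all, prev, rr) {
  stopifnot(all(m_all >= 0), all(prev >= 0), all(rr > 0))
  if (any(prev >= 1 & rr != 1)) {
    stop("split_mortality degenerate: prevalence 1 with rr != 1")
  }
  m_nd <- m_all / (1 + prev * (rr - 1))
  list(m_nondiseased = m_nd, m_diseased = rr * m_nd)
}

#' Back-calculate incidence from prevalence and mortality
#'
#' DisMod-style deterministic inversion of the illness-death balance
#' dP/da = i (1 - P) - P (1 - P) (m_d - m_nd) on band midpoints, with the
#' mortality split from [split_mortality()]. Remission is fixed at zero
#' (non-reversibility). The first band's incidence is solved from the
#' disease-free-entry condition P(entry_age) = 0; each interior band's from
#' the forward difference between its midpoint and the next, with the
#' balance evaluated at the segment's mean prevalence (centred evaluation
#' keeps the inversion within the 5% oracle bound over 10-year segments);
#' the open-ended last band, having no next midpoint, from the zero-gradient
#' steady state. Negative solutions
#' (prevalence falling faster than excess mortality explains) are floored at
#' zero with a warning naming the stratum.
#'
#' @param prev proportion `strat_table` of disease prevalence.
#' @param m_all rate `strat_table` of all-cause mortality.
#' @param rr_mortality named numeric vector per band (see
#'   [model_parameters()]).
#' @param entry_age age of disease-free entry (years).
#' @return rate `strat_table` of incidence per disease-free person-year.
#' @export
backcalculate_incidence <- function(prev, m_all, rr_mortality,
                                    entry_age = 25) {
  stopifnot(inherits(prev, "strat_table"), prev$kind == "proportion",
            inherits(m_all, "strat_table"), m_all$kind == "rate",
            identical(band_labels(prev), band_labels(m_all)))
  bands <- parse_age_bands(band_labels(prev))
  rr <- rr_mortality[band_labels(prev)]
  if (anyNA(rr)) stop("rr_mortality must name every band")
  out <- prev$values * NA_real_
  for (sex in SEXES) {
    p <- prev$values[, sex]
    sp <- split_mortality(m_all$values[, sex], p, rr)
    excess <- sp$m_diseased - sp$m_nondiseased
    n <- length(p)
    for (b in seq_len(n)) {
      if (b == 1) {
        # disease-free entry: P rises from 0 at entry_age to p[1] at the
        # first midpoint
        dp <- p[1] / (bands$midpoint[1] - entry_age)
        pbar <- p[1] / 2
      } else if (b < n) {
        dp <- (p[b + 1] - p[b]) / (bands$midpoint[b + 1] - bands$midpoint[b])
        pbar <- (p[b] + p[b + 1]) / 2
      } else {
        dp <- 0  # open-ended band: zero-gradient steady state
        pbar <- p[b]
      }
      i <- (dp + pbar * (1 - pbar) * excess[b]) / (1 - pbar)
      if (i < 0) {
        warning(sprintf(
          "negative back-calculated incidence floored at 0 for (%s, %s)",
          sex, bands$label[b]))
        i <- 0
      }
      out[b, sex] <- i
    }
  }
  strat_table(out, "rate", "per disease-free person-year")
}

#' Forward illness-death integration (independent oracle)
#'
#' Integrates the same illness-death system as [backcalculate_incidence()]
#' forward in 1-year age steps from P(entry_age) = 0. Band rates are laid on
#' the age axis with the same discretisation convention the back-calculation
#' inverts: band b's rates govern the segment from its midpoint to the next
#' band's midpoint (the first band's from the entry age). Used as the
#' brute-force oracle for the back-calculation and as the steady-state
#' prevalence generator of the synthetic-data module.
#'
#' @param incidence,m_all rate `strat_table`s on one banding.
#' @param rr_mortality named numeric per-band relative mortality.
#' @param entry_age entry age (years), disease-free.
#' @param max_age last integrated age.
#' @return proportion `strat_table` of prevalence at band midpoints; the full
#'   single-year age series is attached as attribute `"ages"` (matrix with
#'   columns `age`, `men`, `women`).
#' @export
forward_prevalence <- function(incidence, m_all, rr_mortality,
                               entry_age = 25, max_age = 85) {
  stopifnot(inherits(incidence, "strat_table"), incidence$kind == "rate",
            identical(band_labels(incidence), band_labels(m_all)))
  bands <- parse_age_bands(band_labels(incidence))
  rr <- rr_mortality[band_labels(incidence)]
  ages <- entry_age:max_age
  # midpoint-delimited segments: band b's rates govern [midpoint_b,
  # midpoint_{b+1}), the first band's from entry_age
  seg <- pmax(findInterval(ages, bands$midpoint), 1)
  series <- matrix(NA_real_, length(ages), 2, dimnames = list(NULL, SEXES))
  out <- incidence$values * NA_real_
  for (sex in SEXES) {
    p <- 0
    for (k in seq_along(ages)) {
      series[k, sex] <- p
      b <- seg[k]
      sp <- split_mortality(m_all$values[b, sex], p, rr[b])
      ex <- sp$m_diseased - sp$m_nondiseased
      p <- p + incidence$values[b, sex] * (1 - p) - p * (1 - p) * ex
      p <- min(max(p, 0), 1)
    }
    out[, sex] <- stats::approx(ages, series[, sex], xout = bands$midpoint,
                                rule = 2)$y
  }
  res <- strat_table(out, "proportion")
  attr(res, "ages") <- cbind(age = ages, series)
  res
}

#' Partition population incidence across exposure pools
#'
#' Splits the disease-free population incidence `i_pop` into pool-specific
#' rates proportional to the incidence relative risks, preserving the
#' population-average identity sum(share_k * i_k) == i_pop exactly:
#' `i_healthy = i_pop / sum(share_k * rr_k)`, `i_k = rr_k * i_healthy`.
#'
#' @param i_pop population incidence among the disease-free.
#' @param pool_shares named numeric over `healthy, obese, smoker,
#'   obese_smoker`, summing to 1.
#' @param rr_incidence named relative risks (healthy = 1), as in
#'   [model_parameters()].
#' @return named numeric vector of per-pool incidence rates.
#' @export
partition_incidence <- function(i_pop, pool_shares, rr_incidence) {
  stopifnot(all(POOLS %in% names(pool_shares)),
            all(POOLS %in% names(rr_incidence)))
  s <- pool_shares[POOLS]
  if (sum(s) <= 0) stop("partition_incidence: all pool shares zero")
  s <- s / sum(s)
  rr <- rr_incidence[POOLS]
  i_h <- i_pop / sum(s * rr)
  stats::setNames(rr * i_h, POOLS)
}

#' Build the per-anchor disease-rate schedule
#'
#' For each anchor survey: scale the all-cause mortality schedule (referenced
#' at the first anchor year) to the anchor year with the secular
#' mortality-improvement factor, split it by T2D status at that anchor's
#' prevalence, and back-calculate the population incidence from the anchor
#' prevalence. These rates define the "regime" in force from that anchor
#' until the next one; within a regime the engine continues the secular
#' improvement year by year.
#'
#' @param inputs a [study_inputs()].
#' @param parameters a [model_parameters()]; defaults to the bundle carried
#'   by `inputs`.
#' @return named list (by anchor year) of lists with elements `i_pop`,
#'   `m_nondiseased`, `m_diseased` (all `strat_table`s), `rr_mortality` and
#'   `year`.
#' @export
build_disease_rates <- function(inputs, parameters = inputs$parameters) {
  rr <- parameters$rr_mortality
  ref_year <- anchor_years(inputs)[1]
  out <- list()
  for (snap in inputs$anchor_surveys) {
    fac <- (1 - parameters$mortality_improvement)^(snap$year - ref_year)
    m <- strat_table(inputs$mortality$values * fac, "rate",
                     inputs$mortality$units)
    sp_nd <- m$values * NA_real_
    sp_d <- m$values * NA_real_
    for (sex in SEXES) {
      sp <- split_mortality(m$values[, sex], snap$t2d$values[, sex],
                            rr[band_labels(m)])
      sp_nd[, sex] <- sp$m_nondiseased
      sp_d[, sex] <- sp$m_diseased
    }
    i_pop <- backcalculate_incidence(snap$t2d, m, rr)
    if (parameters$incidence_scale != 1) {
      i_pop <- strat_table(i_pop$values * parameters$incidence_scale,
                           "rate", i_pop$units)
    }
    out[[as.character(snap$year)]] <- list(
      i_pop = i_pop,
      m_nondiseased = strat_table(sp_nd, "rate", "per person-year"),
      m_diseased = strat_table(sp_d, "rate", "per person-year"),
      rr_mortality = rr[band_labels(m)], year = snap$year)
  }
  out
}
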