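#' Survey snapshots and study inputs
#'
#' A `survey_snapshot` bundles one cross-sectional survey year: population
#' counts plus T2D, obesity and smoking prevalence, all on one banding.
#' `study_inputs` bundles everything a model run needs: the ordered anchor
#' surveys, demographic anchors out to the horizon, the all-cause mortality
#' schedule and the epidemiological parameters.
#'
#' @param year calendar year (1900-2100).
#' @param population count `strat_table` (thousands).
#' @param t2d,obesity,smoking proportion `strat_table`s.
#' @return an object of class `survey_snapshot`.
#' @export
survey_snapshot <- function(year, population, t2d, obesity, smoking) {
  stopifnot(year >= 1900, year <= 2100,
            inherits(population, "strat_table"), population$kind == "count")
  tabs <- list(t2d = t2d, obesity = obesity, smoking = smoking)
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    stopifnot(inherits(tb, "strat_table"))
    if (tb$kind != "proportion") stop(nm, " table must be a proportion")
    if (!identical(band_labels(tb), band_labels(population))) {
      stop("snapshot tables must share one banding (", nm, " differs)")
    }
  }
  structure(list(year = as.integer(year), population = population,
                 t2d = t2d, obesity = obesity, smoking = smoking),
            class = "survey_snapshot")
}

#' @rdname survey_snapshot
#' @param anchor_surveys list of `survey_snapshot`, strictly increasing years.
#' @param demography named list of count `strat_table`s; names are calendar
#'   years; must include every anchor year and the horizon (intermediate
#'   years are filled by [interpolate_demography()]).
#' @param mortality all-cause mortality rate `strat_table` (per person-year).
#' @param horizon_year last simulated calendar year.
#' @param parameters a [model_parameters()] bundle.
#' @export
study_inputs <- function(anchor_surveys, demography, mortality, horizon_year,
                         parameters = model_parameters()) {
  stopifnot(length(anchor_surveys) >= 1)
  yrs <- vapply(anchor_surveys, function(s) s$year, 0L)
  if (is.unsorted(yrs, strictly = TRUE)) {
    stop("anchor years must be strictly increasing")
  }
  if (horizon_year < max(yrs)) stop("horizon must be at or after last anchor")
  dy <- as.integer(names(demography))
  if (anyNA(dy)) stop("demography list must be named by calendar year")
  if (!all(c(yrs, horizon_year) %in% dy)) {
    stop("demography must cover every anchor year and the horizon")
  }
  stopifnot(inherits(mortality, "strat_table"), mortality$kind == "rate")
  structure(list(anchor_surveys = anchor_surveys,
                 demography = demography[order(dy)],
                 mortality = mortality,
                 horizon_year = as.integer(horizon_year),
                 parameters = parameters),
            class = "study_inputs")
}

#' @rdname survey_snapshot
#' @param inputs a `study_inputs`.
#' @export
anchor_years <- function(inputs) {
  vapply(inputs$anchor_surveys, function(s) s$year, 0L)
}

#' Interpolate the demographic series
#'
#' Per-stratum geometric interpolation of population counts between the
#' nearest bracketing demographic anchors; exact at anchors. Geometric
#' interpolation matches the constant-relative-growth convention used for the
#' risk-factor trends and guarantees positivity.
#'
#' @param inputs a [study_inputs()].
#' @param year calendar year between the first demographic anchor and the
#'   horizon.
#' @return a count `strat_table`.
#' @export
interpolate_demography <- function(inputs, year) {
  dy <- as.integer(names(inputs$demography))
  if (year < min(dy) || year > inputs$horizon_year) {
    stop("year ", year, " outside covered demographic range")
  }
  if (year %in% dy) return(inputs$demography[[as.character(year)]])
  lo <- max(dy[dy < year]); hi <- min(dy[dy > year])
  a <- inputs$demography[[as.character(lo)]]$values
  b <- inputs$demography[[as.character(hi)]]$values
  f <- (year - lo) / (hi - lo)
  strat_table(a * (b / a)^f, "count",
              inputs$demography[[as.character(lo)]]$units)
}
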