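#' Harmonize an observed survey onto the model banding
#'
#' Later surveys may not cover the youngest and oldest model bands (the 2005
#' Tunisian survey covered ages 35-74 only). Missing edge bands of the
#' prevalence tables are filled by copying the adjacent band, and the imputed
#' cells are flagged. Only edge imputation is supported; interior gaps are an
#' error. A diagnostic-threshold note records the glucose-criterion
#' equivalence assumed when comparing surveys (fasting plasma glucose >= 7
#' mmol/l treated as equivalent to capillary >= 6.1 mmol/l).
#'
#' @param survey a [survey_snapshot()] whose prevalence tables may contain
#'   `NA` in edge bands (build them with `allow_na = TRUE` via
#'   [partial_snapshot()]).
#' @return a complete `survey_snapshot` with attributes `imputed` (logical
#'   band x sex x table array) and `threshold_note`.
#' @export
harmonize_observed <- function(survey) {
  tabs <- c("t2d", "obesity", "smoking")
  bl <- band_labels(survey$population)
  imputed <- array(FALSE, c(length(bl), 2, length(tabs)),
                   dimnames = list(bl, SEXES, tabs))
  for (nm in tabs) {
    m <- survey[[nm]]$values
    for (sex in SEXES) {
      v <- m[, sex]
      miss <- is.na(v)
      if (!any(miss)) next
      obs <- which(!miss)
      if (!length(obs)) stop("harmonize_observed: no observed band for ", sex)
      if (!all(which(miss) < min(obs) | which(miss) > max(obs))) {
        stop("harmonize_observed: interior gap in (", sex, ", ", nm,
             "); only edge imputation is supported")
      }
      for (b in rev(seq_len(min(obs) - 1))) v[b] <- v[b + 1]
      for (b in seq(min(max(obs) + 1, length(v) + 1),
                    length.out = max(0, length(v) - max(obs)))) {
        v[b] <- v[b - 1]
      }
      m[, sex] <- v
      imputed[miss, sex, nm] <- TRUE
    }
    survey[[nm]] <- strat_table(m, "proportion", survey[[nm]]$units)
  }
  attr(survey, "imputed") <- imputed
  attr(survey, "threshold_note") <-
    "fasting plasma glucose >= 7 mmol/l treated as equivalent to capillary >= 6.1 mmol/l"
  survey
}

#' @rdname harmonize_observed
#' @inheritParams survey_snapshot
#' @return `partial_snapshot()`: a `survey_snapshot` that tolerates `NA`
#'   prevalence cells (for later harmonization).
#' @export
partial_snapshot <- function(year, population, t2d, obesity, smoking) {
  snap <- list(year = as.integer(year), population = population,
               t2d = t2d, obesity = obesity, smoking = smoking)
  class(snap) <- "survey_snapshot"
  snap
}

#' Hindcast validation against an observed survey
#'
#' Compares the model's population-weighted T2D prevalence at the observed
#' survey's year with the observed prevalence, per sex and overall. The
#' modelled overall figure is weighted by the model's live population; the
#' observed by the survey's population table.
#'
#' @param run a [run_model()] result covering the observed year.
#' @param observed a complete [survey_snapshot()].
#' @return data.frame of class `validation_report` with columns `sex`,
#'   `modelled`, `observed`, `difference_pp` (modelled minus observed,
#'   percentage points).
#' @export
validate_run <- function(run, observed) {
  yrs <- vapply(run$states, function(s) s$year, 0L)
  if (!observed$year %in% yrs) {
    stop("observed year ", observed$year, " not simulated")
  }
  rows <- lapply(c(SEXES, "total"), function(sex) {
    mod <- run_prevalence(run, observed$year, sex)
    obs <- weighted_total(observed$t2d, observed$population,
                         if (sex == "total") NULL else sex)
    data.frame(sex = sex, modelled = 100 * mod, observed = 100 * obs,
               difference_pp = 100 * (mod - obs))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' Projection summary tables
#'
#' Per listed year: T2D prevalence (%) by sex and total, and T2D counts
#' (thousands), in the shape of a scenario-projection table.
#'
#' @param run a [run_model()] result.
#' @param years calendar years to tabulate (subset of the simulated years).
#' @param digits decimals for the prevalence columns.
#' @return data.frame with one row per year.
#' @export
summary_tables <- function(run, years, digits = 1) {
  sim <- unique(run$summary$year)
  if (!all(years %in% sim)) stop("summary_tables: year(s) not simulated")
  rows <- lapply(years, function(y) {
    s <- run$summary[run$summary$year == y, ]
    g <- function(sex, col) s[s$sex == sex, col]
    data.frame(year = y,
               men_pct = round(100 * g("men", "prevalence"), digits),
               women_pct = round(100 * g("women", "prevalence"), digits),
               total_pct = round(100 * g("total", "prevalence"), digits),
               t2d_count_thousand = g("total", "t2d"),
               live_thousand = g("total", "live"))
  })
  if (!length(rows)) {
    return(data.frame(year = integer(), men_pct = numeric(),
                      women_pct = numeric(), total_pct = numeric(),
                      t2d_count_thousand = numeric(),
                      live_thousand = numeric()))
  }
  do.call(rbind, rows)
}
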