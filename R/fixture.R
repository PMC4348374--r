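#' The packaged Tunisian study inputs
#'
#' Loads the Tunisian 1997 and 2005 survey anchors (population, T2D, obesity
#' and smoking prevalence by sex and 10-year age band), the 2027 demographic
#' anchor, the all-cause mortality schedule and the epidemiological
#' parameters from the CSV/YAML files shipped under
#' `inst/extdata/tunisia/`. Files flagged `source: assumption` in their
#' comment headers (mortality, 2027 per-band demography, relative risks)
#' carry documented placeholder values; substitute official data via a
#' custom `dir`.
#'
#' @param dir directory holding a `config.yaml` manifest and the input files
#'   it names (defaults to the packaged fixture).
#' @return a [study_inputs()].
#' @examples
#' inp <- tunisia_inputs()
#' weighted_total(inp$anchor_surveys[[1]]$t2d,
#'                inp$anchor_surveys[[1]]$population)
#' @export
tunisia_inputs <- function(dir = system.file("extdata", "tunisia",
                                             package = "t2dmarkov")) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  snap_of <- function(a) {
    survey_snapshot(
      a$year,
      read_stratified_csv(file.path(dir, a$population), "count",
                          "thousand persons"),
      read_stratified_csv(file.path(dir, a$t2d), "proportion"),
      read_stratified_csv(file.path(dir, a$obesity), "proportion"),
      read_stratified_csv(file.path(dir, a$smoking), "proportion"))
  }
  anchors <- lapply(cfg$anchors, snap_of)
  demog <- lapply(cfg$demography, function(f) {
    read_stratified_csv(file.path(dir, f), "count", "thousand persons")
  })
  names(demog) <- names(cfg$demography)
  pars <- yaml::read_yaml(file.path(dir, cfg$parameters))
  parameters <- model_parameters(
    rr_mortality = unlist(pars$rr_mortality),
    rr_incidence = unlist(pars$rr_incidence),
    bounds_rel = pars$bounds_rel,
    mortality_improvement = pars$mortality_improvement)
  study_inputs(anchors, demog,
               read_stratified_csv(file.path(dir, cfg$mortality), "rate",
                                   "per person-year"),
               cfg$horizon_year, parameters)
}

#' @rdname tunisia_inputs
#' @return `tunisia_observed_2005()`: the published survey-weighted observed
#'   T2D prevalences (percent) of the 2005 survey, used for hindcast
#'   comparison. These differ slightly from the crude band-weighted means of
#'   the printed age-band cells.
#' @export
tunisia_observed_2005 <- function() {
  c(men = 16.1, women = 14.1, total = 15.2)
}
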