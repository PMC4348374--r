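#' Age-band utilities
#'
#' The model is stratified by sex and 10-year age bands. Bands are closed-open
#' intervals `[lower, upper + 1)` in whole years; the last band is open-ended
#' (e.g. "75+"). The default banding matches the Tunisian survey tables:
#' 25-34, 35-44, 45-54, 55-64, 65-74, 75+.
#'
#' @param labels character vector of band labels, e.g. `c("25-34", "75+")`.
#' @return `parse_age_bands()`: a data.frame with columns `label`, `lower`,
#'   `upper` (Inf for the open band), `width` (years; Inf for the open band)
#'   and `midpoint` (the open band's midpoint assumes a nominal 10-year span).
#' @examples
#' parse_age_bands(default_age_bands())
#' @export
parse_age_bands <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1)
  open <- grepl("\\+$", labels)
  lower <- as.integer(sub("[-+].*$", "", labels))
  upper <- rep(Inf, length(labels))
  upper[!open] <- as.integer(sub("^[0-9]+-", "", labels[!open]))
  if (anyNA(lower) || anyNA(upper[!open])) {
    stop("unparseable age-band label(s): ",
         paste(labels[is.na(lower)], collapse = ", "))
  }
  if (any(open[-length(labels)])) {
    stop("only the last age band may be open-ended")
  }
  if (!open[length(labels)]) {
    stop("the last age band must be open-ended (e.g. \"75+\")")
  }
  width <- ifelse(open, Inf, upper - lower + 1)
  # contiguity: next lower == this upper + 1
  if (length(labels) > 1) {
    nxt <- lower[-1]
    end <- upper[-length(labels)] + 1
    if (any(nxt != end)) stop("age bands must be contiguous and ordered")
  }
  midpoint <- ifelse(open, lower + 5, (lower + upper + 1) / 2)
  data.frame(label = labels, lower = lower, upper = upper,
             width = width, midpoint = midpoint,
             stringsAsFactors = FALSE)
}

#' @rdname parse_age_bands
#' @export
default_age_bands <- function() {
  c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")
}

#' @rdname parse_age_bands
#' @param age numeric age in years.
#' @param bands parsed band table from [parse_age_bands()].
#' @return `band_of_age()`: integer index of the band containing `age`.
#' @export
band_of_age <- function(age, bands) {
  idx <- findInterval(age, c(bands$lower, Inf))
  idx[age < bands$lower[1]] <- NA_integer_
  pmin(idx, nrow(bands))
}
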