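#' Stratified tables
#'
#' The universal container for age/sex-stratified quantities: a numeric matrix
#' with one row per age band and columns `men`, `women`, plus a quantity kind
#' (`count`, `proportion` or `rate`) and free-text units. Proportions are
#' stored internally on the 0-1 scale (CSV files carry percentages, as survey
#' tables print them).
#'
#' @param values numeric matrix, rows = age bands (rownames = band labels),
#'   columns `men` and `women`.
#' @param kind one of `"count"`, `"proportion"`, `"rate"`.
#' @param units free-text units (e.g. `"thousand persons"`).
#' @return an object of class `strat_table`.
#' @export
strat_table <- function(values, kind = c("proportion", "count", "rate"),
                        units = "") {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) && ncol(values) == 2) colnames(values) <- SEXES
  if (!identical(colnames(values), SEXES)) {
    stop("strat_table columns must be 'men', 'women'")
  }
  if (is.null(rownames(values))) stop("strat_table rows must be band labels")
  parse_age_bands(rownames(values))  # validates the banding
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell (%s, %s)", colnames(values)[bad[2]],
                 rownames(values)[bad[1]]))
  }
  if (any(values < 0)) stop("negative value in ", kind, " table")
  if (kind == "proportion" && any(values > 1)) {
    stop("proportion above 1 in table (did you forget the percent scale?)")
  }
  structure(list(values = values, kind = kind, units = units),
            class = "strat_table")
}

#' @export
print.strat_table <- function(x, ...) {
  cat(sprintf("<strat_table: %s%s>\n", x$kind,
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  print(round(x$values, 5))
  invisible(x)
}

#' @rdname strat_table
#' @param x a `strat_table`.
#' @export
band_labels <- function(x) rownames(x$values)

#' Read / write stratified CSV tables
#'
#' Schema: a comma-separated UTF-8 file with dot decimals, optional `#`
#' comment lines, a header `age_band,men,women`, and one row per age band.
#' Files holding proportions carry percentages (as printed in survey tables)
#' and are converted to 0-1 proportions on read; [write_stratified_csv()]
#' converts back, so a write/read round trip reproduces every cell.
#'
#' @param path file path.
#' @param kind quantity kind, see [strat_table()].
#' @param units free-text units attached to the result.
#' @return a [strat_table()].
#' @export
read_stratified_csv <- function(path, kind = c("proportion", "count", "rate"),
                                units = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE)
  need <- c("age_band", SEXES)
  if (!all(need %in% names(df))) {
    stop("schema error in ", path, ": header must name ",
         paste(need, collapse = ", "))
  }
  m <- as.matrix(df[, SEXES])
  rownames(m) <- df$age_band
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("schema error in %s: missing cell (%s, %s)", path,
                 SEXES[bad[2]], df$age_band[bad[1]]))
  }
  if (any(m < 0)) stop("validation error in ", path, ": negative value")
  if (kind == "proportion") {
    m <- m / 100
    if (any(m > 1)) {
      stop("validation error in ", path, ": proportion above 1 after ",
           "percent conversion")
    }
  }
  strat_table(m, kind, units)
}

#' @rdname read_stratified_csv
#' @param tab a [strat_table()] to write.
#' @param comment optional character vector written as `#` header lines.
#' @export
write_stratified_csv <- function(tab, path, comment = NULL) {
  stopifnot(inherits(tab, "strat_table"))
  m <- tab$values
  if (tab$kind == "proportion") m <- m * 100
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.csv(data.frame(age_band = rownames(m), m, check.names = FALSE,
                              row.names = NULL),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population-weighted total of a stratified prevalence
#'
#' Crude weighted mean sum(prev * pop) / sum(pop) over the selected strata,
#' as used for the "Total" rows of survey tables.
#'
#' @param prev a proportion (or rate) `strat_table`.
#' @param pop a count `strat_table` on the same banding.
#' @param sex `"men"`, `"women"`, or `NULL` for both sexes combined.
#' @return a single number on the same scale as `prev`.
#' @export
weighted_total <- function(prev, pop, sex = NULL) {
  stopifnot(inherits(prev, "strat_table"), inherits(pop, "strat_table"),
            pop$kind == "count")
  if (!identical(band_labels(prev), band_labels(pop))) {
    stop("weighted_total: tables must share one banding")
  }
  cols <- if (is.null(sex)) SEXES else match.arg(sex, SEXES)
  w <- pop$values[, cols, drop = FALSE]
  p <- prev$values[, cols, drop = FALSE]
  tot <- sum(w)
  if (tot <= 0) stop("weighted_total: zero total population")
  sum(p * w) / tot
}
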