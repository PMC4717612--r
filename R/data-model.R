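#' Construct a measurement-error series
#'
#' One published series of paired measurements, summarized by its sample
#' size, mean error and SD of error (all errors in g/dL).  A series may
#' carry a second block of aggregates obtained after an initial per-patient
#' calibration of the device.
#'
#' @param label Non-empty text identifier, unique within a dataset.
#' @param n Integer number of paired measurements (>= 2).
#' @param m Mean error (device minus reference), g/dL.
#' @param s SD of error, g/dL (> 0).
#' @param n_c,m_c,s_c Optional calibrated-mode aggregates; either all three
#'   present or all `NA`.  `n_c` may differ from `n` (some sources report
#'   calibrated aggregates on a subset of the raw sample).
#' @return An object of class `aggregate_series`.
#' @export
aggregate_series <- function(label, n, m, s, n_c = NA, m_c = NA, s_c = NA) {
  x <- structure(
    list(label = as.character(label), n = as.integer(n),
         m = as.numeric(m), s = as.numeric(s),
         n_c = suppressWarnings(as.integer(n_c)),
         m_c = as.numeric(m_c), s_c = as.numeric(s_c)),
    class = "aggregate_series")
  x
}

#' @export
print.aggregate_series <- function(x, ...) {
  cat(sprintf("<series> %s: n=%d, m=%.2f, s=%.2f", x$label, x$n, x$m, x$s))
  if (has_calibrated(x))
    cat(sprintf(" | calibrated: n=%d, m=%.2f, s=%.2f", x$n_c, x$m_c, x$s_c))
  cat("\n")
  invisible(x)
}

#' Does a series carry calibrated aggregates?
#' @param x An `aggregate_series`.
#' @return Logical scalar.
#' @export
has_calibrated <- function(x) {
  !is.na(x$n_c) && !is.na(x$m_c) && !is.na(x$s_c)
}

#' Assemble a dataset of measurement-error series
#'
#' @param series List of [aggregate_series()] objects.
#' @param provenance Free-text description of where the aggregates come
#'   from; echoed into output reports.
#' @return An object of class `error_dataset`.  Units are fixed to g/dL.
#' @export
error_dataset <- function(series, provenance = "") {
  stopifnot(length(series) >= 1)
  d <- structure(list(series = series, units = "g/dL",
                      provenance = provenance),
                 class = "error_dataset")
  viol <- validate_dataset(d)
  if (nrow(viol) > 0L)
    stop("invalid dataset:\n", paste(sprintf("  %s/%s: %s", viol$label,
         viol$field, viol$rule), collapse = "\n"), call. = FALSE)
  d
}

#' @export
print.error_dataset <- function(x, ...) {
  k <- sum(vapply(x$series, has_calibrated, logical(1)))
  cat(sprintf("<error_dataset> %d series (%d with calibrated aggregates), units %s\n",
              length(x$series), k, x$units))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.error_dataset <- function(x) length(x$series)

#' Coerce a dataset to a data frame (one row per series)
#' @param x An `error_dataset`.
#' @param ... Unused.
#' @export
as.data.frame.error_dataset <- function(x, ...) {
  data.frame(
    label = vapply(x$series, `[[`, character(1), "label"),
    n = vapply(x$series, `[[`, integer(1), "n"),
    m = vapply(x$series, `[[`, numeric(1), "m"),
    s = vapply(x$series, `[[`, numeric(1), "s"),
    n_c = vapply(x$series, function(z) as.integer(z$n_c), integer(1)),
    m_c = vapply(x$series, `[[`, numeric(1), "m_c"),
    s_c = vapply(x$series, `[[`, numeric(1), "s_c"),
    stringsAsFactors = FALSE)
}

#' Validate a dataset against the type invariants
#'
#' Reporting operation: never throws.  Rules checked per series: `n >= 2`,
#' `s > 0`, calibrated block all-or-none with `n_c >= 2`, `s_c > 0`,
#' finite numbers, non-empty unique labels.
#'
#' @param d An `error_dataset` (or a bare list with a `series` field).
#' @return A data frame with columns `label`, `field`, `rule`; zero rows
#'   iff the dataset is valid.
#' @export
validate_dataset <- function(d) {
  out <- list()
  add <- function(label, field, rule)
    out[[length(out) + 1L]] <<- data.frame(label = label, field = field,
                                           rule = rule)
  labs <- vapply(d$series, `[[`, character(1), "label")
  for (x in d$series) {
    if (!nzchar(x$label)) add(x$label, "label", "label non-empty")
    if (is.na(x$n) || x$n < 2L) add(x$label, "n", "n >= 2")
    if (is.na(x$m) || !is.finite(x$m)) add(x$label, "m", "m finite")
    if (is.na(x$s) || !(x$s > 0)) add(x$label, "s", "s > 0")
    partial <- c(!is.na(x$n_c), !is.na(x$m_c), !is.na(x$s_c))
    if (any(partial) && !all(partial))
      add(x$label, "calibrated", "calibrated block all-or-none")
    if (has_calibrated(x)) {
      if (x$n_c < 2L) add(x$label, "n_c", "n_c >= 2")
      if (!(x$s_c > 0)) add(x$label, "s_c", "s_c > 0")
    }
  }
  dup <- unique(labs[duplicated(labs)])
  for (lb in dup) add(lb, "label", "label unique")
  if (length(out) == 0L)
    return(data.frame(label = character(), field = character(),
                      rule = character()))
  do.call(rbind, out)
}

#' Parse a delimited table of series aggregates
#'
#' Expects a header naming at least `label,n,m,s`; optional columns
#' `n_c,m_c,s_c` hold the calibrated block (rows with empty calibrated
#' cells yield series without one).  Decimal separator is ".", encoding
#' UTF-8.
#'
#' @param source Path to a CSV file, or a connection.
#' @param sep Field separator (default ",").
#' @param provenance Provenance string attached to the dataset; defaults to
#'   the file path.
#' @return An `error_dataset`.
#' @export
parse_series_table <- function(source, sep = ",", provenance = NULL) {
  df <- tryCatch(
    utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", stringsAsFactors = FALSE,
                      encoding = "UTF-8", check.names = TRUE),
    error = function(e) stop("cannot read series table: ",
                             conditionMessage(e), call. = FALSE))
  need <- c("label", "n", "m", "s")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  opt <- c("n_c", "m_c", "s_c")
  for (cn in setdiff(opt, names(df))) df[[cn]] <- NA_character_
  num <- function(v, col) {
    v <- trimws(v)
    v[v == ""] <- NA_character_
    x <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(x))
    if (length(bad))
      stop(sprintf("malformed number in column '%s', row %d: '%s'",
                   col, bad[1], v[bad[1]]), call. = FALSE)
    x
  }
  series <- lapply(seq_len(nrow(df)), function(i) {
    aggregate_series(label = trimws(df$label[i]),
                     n = num(df$n[i], "n"), m = num(df$m[i], "m"),
                     s = num(df$s[i], "s"), n_c = num(df$n_c[i], "n_c"),
                     m_c = num(df$m_c[i], "m_c"), s_c = num(df$s_c[i], "s_c"))
  })
  if (is.null(provenance))
    provenance <- if (is.character(source)) source else "connection"
  d <- structure(list(series = series, units = "g/dL",
                      provenance = provenance), class = "error_dataset")
  viol <- validate_dataset(d)
  if (nrow(viol) > 0L)
    stop("validation error:\n",
         paste(sprintf("  %s/%s: %s", viol$label, viol$field, viol$rule),
               collapse = "\n"), call. = FALSE)
  d
}

#' Serialize a dataset to CSV
#'
#' Writes the same dialect [parse_series_table()] reads; numeric fields are
#' formatted to 2 decimals (the precision of the source tables) so that a
#' parse/serialize round trip is text-stable.
#'
#' @param d An `error_dataset`.
#' @param path Output file path.
#' @param digits Decimal places for m and s columns.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(d, path, digits = 2) {
  df <- as.data.frame(d)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = digits,
                                                  format = "f"))
  out <- data.frame(label = df$label, n = df$n,
                    m = fmt(df$m), s = fmt(df$s),
                    n_c = ifelse(is.na(df$n_c), "", df$n_c),
                    m_c = fmt(df$m_c), s_c = fmt(df$s_c))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled literature dataset of SpHb measurement errors
#'
#' 34 series of perioperative SpHb-vs-tHb error aggregates extracted from
#' 21 publications, 5 series with calibrated-mode aggregates, exactly as
#' printed in the source table (2 decimals).  Sub-series of one paper
#' (e.g. pre/post-operative phases) are independent rows.
#'
#' @return An `error_dataset` with 34 series.
#' @export
bundled_literature_dataset <- function() {
  path <- system.file("extdata", "sphb_series.csv", package = "errmeta",
                      mustWork = TRUE)
  parse_series_table(path, provenance = "bundled SpHb literature table (34 series)")
}
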