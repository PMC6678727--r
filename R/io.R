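#' Read a grey series from a delimited text file
#'
#' Expects two columns named `period` and `value` (a header row), comma
#' separated by default. Rows are validated: values must be numeric and
#' non-negative, periods integer, strictly increasing and consecutive;
#' violations are reported with the offending line number.
#'
#' @param path path to the file.
#' @param delimiter field separator, default `","`.
#' @return a `grey_series`.
#' @examples
#' read_series(system.file("extdata", "china_so2.csv", package = "greymtd"))
#' @export
read_series <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    stop_grey("io", sprintf("input file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) stop_grey("parse", sprintf(
      "cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L) {
    stop_grey("empty_series", sprintf("no data rows in %s", path))
  }
  if (ncol(df) < 2L) {
    stop_grey("parse", "expected two columns: period, value")
  }
  per <- suppressWarnings(as.numeric(df[[1L]]))
  val <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(is.na(per) | is.na(val) | per != round(per))
  if (length(bad)) {
    stop_grey("parse", sprintf(
      "non-numeric or non-integer-period row(s) at line %s",
      paste(bad + 1L, collapse = ", ")))     # +1 for the header line
  }
  neg <- which(val < 0)
  if (length(neg)) {
    stop_grey("negative_value", sprintf(
      "negative value at line %s", paste(neg + 1L, collapse = ", ")))
  }
  if (anyDuplicated(per) || (length(per) > 1L && any(diff(per) != 1))) {
    stop_grey("bad_periods",
              "period labels must be consecutive without duplicates")
  }
  grey_series(val, periods = as.integer(per))
}

#' Write a grey series to a delimited text file
#'
#' @param x a `grey_series` (or numeric vector).
#' @param path output path.
#' @param delimiter field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, delimiter = ",") {
  utils::write.table(as.data.frame(as_grey_series(x)), path,
                     sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a model, backtest or forecast to JSON or an aligned table
#'
#' `format = "json"` writes full-precision JSON that round-trips losslessly;
#' `format = "table"` writes an aligned human-readable text rendering with
#' presentation rounding (values to 3 decimals, MAPE to 2, coefficients
#' to 5).
#'
#' @param x a `gm11`, `gm_backtest` or `gm_forecast` object.
#' @param path output file, or `NULL` to return the text.
#' @param format `"json"` or `"table"`.
#' @return the serialized text, invisibly when written to `path`.
#' @export
write_report <- function(x, path = NULL, format = c("json", "table")) {
  format <- match.arg(format)
  txt <- if (format == "json") {
    jsonlite::toJSON(report_payload(x), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
  } else {
    paste(utils::capture.output(print(x)), collapse = "\n")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Common JSON payload across the three report types.
report_payload <- function(x) {
  if (inherits(x, "gm11")) {
    list(model = list(a = x$a, b = x$b,
                      scale = x$c_scale, offset = x$c_offset,
                      background_mode = x$background_mode),
         membership = as.numeric(x$weights),
         background = as.numeric(x$background),
         series = as.data.frame(x$series))
  } else if (inherits(x, "gm_backtest")) {
    list(window = x$window,
         periods = x$periods, actuals = x$actuals,
         predictions = x$predictions, ape = x$ape,
         mape_percent = 100 * x$mape, grade = as.character(x$grade))
  } else if (inherits(x, "gm_forecast")) {
    list(window = x$window, horizon = x$horizon,
         periods = x$periods, forecasts = x$values,
         provenance = x$provenance)
  } else {
    stop_grey("bad_argument", "unsupported object for write_report")
  }
}
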