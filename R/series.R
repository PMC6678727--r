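#' Construct a grey time series
#'
#' A `grey_series` is an ordered annual (or otherwise consecutively indexed)
#' series of non-negative values — the raw series \eqn{x^{(0)}} of grey
#' modelling. Period labels must be strictly increasing consecutive integers.
#'
#' @param values numeric vector of non-negative observations.
#' @param periods integer vector of period labels, same length as `values`;
#'   defaults to `1:length(values)`.
#' @return An object of class `grey_series`: the numeric values with a
#'   `periods` attribute.
#' @examples
#' grey_series(c(24.681, 23.212, 22.144, 21.851), periods = 2007:2010)
#' @export
grey_series <- function(values, periods = seq_along(values)) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop_grey("empty_series", "a grey series needs at least one observation")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_grey("invalid_value", "series values must be finite and non-missing")
  }
  if (any(values < 0)) {
    stop_grey("negative_value", sprintf(
      "series values must be non-negative (found %g)", min(values)))
  }
  periods <- as.integer(periods)
  if (length(periods) != length(values)) {
    stop_grey("length_mismatch", "periods and values differ in length")
  }
  if (length(periods) > 1L && any(diff(periods) != 1L)) {
    stop_grey("bad_periods",
              "period labels must be strictly increasing and consecutive")
  }
  structure(values, periods = periods, class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat(sprintf("grey series: %d periods (%d-%d)\n",
              length(x), min(periods(x)), max(periods(x))))
  print(stats::setNames(as.numeric(x), periods(x)), ...)
  invisible(x)
}

#' Period labels of a grey series
#'
#' @param x a `grey_series` (a plain numeric vector is labelled `1:n`).
#' @return integer vector of period labels.
#' @export
periods <- function(x) {
  p <- attr(x, "periods")
  if (is.null(p)) seq_along(x) else p
}

#' @export
as.data.frame.grey_series <- function(x, ...) {
  data.frame(period = periods(x), value = as.numeric(x))
}

# Coerce a plain numeric vector (or grey_series) for internal use,
# validating non-negativity on the way in.
as_grey_series <- function(x) {
  if (inherits(x, "grey_series")) x else grey_series(x)
}

#' @export
`[.grey_series` <- function(x, i, ...) {
  grey_series(unclass(x)[i], periods = periods(x)[i])
}

# Structured error signalling: every error class the model layer raises is a
# condition of class c("greymtd_<what>", "greymtd_error", "error").
stop_grey <- function(what, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("greymtd_", what), "greymtd_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}
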