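#' Mean absolute percentage error
#'
#' \eqn{MAPE = \frac{1}{m}\sum_i |\hat y_i - y_i| / y_i}, returned as a
#' fraction; multiply by 100 for percent. All actuals must be strictly
#' positive.
#'
#' @param actuals,predictions numeric vectors of equal length.
#' @return the MAPE as a fraction.
#' @export
mape <- function(actuals, predictions) {
  if (length(actuals) != length(predictions)) {
    stop_grey("length_mismatch", "actuals and predictions differ in length")
  }
  if (length(actuals) < 1L) stop_grey("empty_series", "no test points")
  if (any(actuals == 0)) {
    stop_grey("zero_actual", "MAPE undefined when an actual value is zero")
  }
  mean(abs(predictions - actuals) / abs(actuals))
}

#' Lewis-scale forecast accuracy grade
#'
#' Grades a MAPE (in percent) on the Lewis scale: below 10% highly accurate,
#' 10-20% good, 20-50% reasonable, 50% and above inaccurate. The printed cut
#' points are taken as half-open intervals `[10, 20)` and `[20, 50)`.
#'
#' @param mape_percent MAPE in percent, non-negative.
#' @return an ordered factor with levels `highly_accurate < good <
#'   reasonable < inaccurate`.
#' @examples
#' mape_grade(2.96)
#' @export
mape_grade <- function(mape_percent) {
  if (any(mape_percent < 0)) {
    stop_grey("bad_argument", "MAPE cannot be negative")
  }
  lv <- c("highly_accurate", "good", "reasonable", "inaccurate")
  cut(mape_percent, breaks = c(-Inf, 10, 20, 50, Inf), right = FALSE,
      labels = lv, ordered_result = TRUE)
}

#' One-step-ahead rolling backtest
#'
#' For each period after the first `window` observations, fits the grey model
#' on the `window` preceding *actual* values (membership weights recomputed
#' for every window, since they depend on the window's extremes and
#' variance), predicts one step ahead, and scores the predictions by MAPE
#' with a Lewis-scale grade.
#'
#' @param x numeric vector or `grey_series`, longer than `window`.
#' @param window fitting-window length, at least 4 (the grey minimum).
#' @param ... passed to [gm11()] (e.g. `background`, `lb_skew`).
#' @return An object of class `gm_backtest`: list with `periods`, `actuals`,
#'   `predictions`, `ape` (absolute percentage errors, fractions), `mape`
#'   (fraction), `grade`, `window`, `m` (number of test periods).
#' @examples
#' bt <- gm_backtest(china_so2(), window = 4)
#' print(bt)
#' @export
gm_backtest <- function(x, window = 4L, ...) {
  series <- as_grey_series(x)
  n <- length(series)
  if (window < 4L) stop_grey("bad_argument", "window must be at least 4")
  if (n <= window) {
    stop_grey("insufficient_data", sprintf(
      "series length %d leaves no test points beyond window %d", n, window))
  }
  idx <- (window + 1L):n
  preds <- vapply(idx, function(t) {
    unname(predict(gm11(series[(t - window):(t - 1L)], ...), h = 1L))
  }, numeric(1L))
  actual <- as.numeric(series)[idx]
  ape <- abs(preds - actual) / actual
  m <- mape(actual, preds)
  structure(list(periods = periods(series)[idx], actuals = actual,
                 predictions = preds, ape = ape, mape = m,
                 grade = mape_grade(100 * m), window = window,
                 m = length(idx)),
            class = "gm_backtest")
}

#' @export
print.gm_backtest <- function(x, ...) {
  cat(sprintf("rolling one-step backtest (window %d, %d test periods)\n",
              x$window, x$m))
  print(data.frame(period = x$periods, actual = round(x$actuals, 3),
                   predicted = round(x$predictions, 3),
                   ape_pct = round(100 * x$ape, 2)), row.names = FALSE)
  cat(sprintf("MAPE: %.2f%%  (%s)\n", 100 * x$mape,
              gsub("_", " ", as.character(x$grade))))
  invisible(x)
}

#' Rolling multi-step forecast with forecast-augmented windows
#'
#' The rolling mechanism for medium-term forecasting: starting from the
#' `window` most recent actual observations, repeatedly fit the grey model
#' (membership weights recomputed on the current window), forecast one step,
#' append the forecast to the window and drop its oldest element — `horizon`
#' times. From the second step onward the windows contain forecast values
#' ("forecast-augmented"), which the `provenance` flags record.
#'
#' @param x numeric vector or `grey_series` of length at least `window`.
#' @param window rolling-window length, at least 4.
#' @param horizon number of future steps, at least 1.
#' @param ... passed to [gm11()].
#' @return An object of class `gm_forecast`: list with future `periods`,
#'   forecast `values`, and `provenance` (`"actuals"` for the first step,
#'   `"forecast_augmented"` afterwards).
#' @examples
#' gm_rolling_forecast(china_so2(), window = 4, horizon = 5)
#' @export
gm_rolling_forecast <- function(x, window = 4L, horizon = 1L, ...) {
  series <- as_grey_series(x)
  n <- length(series)
  if (window < 4L) stop_grey("bad_argument", "window must be at least 4")
  if (n < window) {
    stop_grey("insufficient_data",
              sprintf("series length %d shorter than window %d", n, window))
  }
  if (horizon < 1L) stop_grey("bad_argument", "horizon must be at least 1")
  win <- as.numeric(series)[(n - window + 1L):n]
  vals <- numeric(horizon)
  for (step in seq_len(horizon)) {
    fit <- tryCatch(gm11(win, ...), greymtd_error = function(e) {
      stop_grey("rolling_step", sprintf(
        "rolling forecast failed at step %d: %s", step, conditionMessage(e)))
    })
    vals[step] <- unname(predict(fit, h = 1L))
    win <- c(win[-1L], vals[step])
  }
  structure(list(periods = periods(series)[n] + seq_len(horizon),
                 values = vals,
                 provenance = c("actuals",
                                rep("forecast_augmented", horizon - 1L)),
                 window = window, horizon = horizon),
            class = "gm_forecast")
}

#' @export
print.gm_forecast <- function(x, ...) {
  cat(sprintf("rolling grey forecast (window %d, horizon %d)\n",
              x$window, x$horizon))
  print(data.frame(period = x$periods, forecast = round(x$values, 3),
                   window_contents = x$provenance), row.names = FALSE)
  invisible(x)
}
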