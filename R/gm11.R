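#' Accumulated generating operation (AGO)
#'
#' Cumulative sums of the raw series: \eqn{x^{(1)}(k) = \sum_{i \le k}
#' x^{(0)}(i)}. Accumulation reveals the exponential regularity the grey
#' model fits; [iago()] is its exact inverse.
#'
#' @param x numeric vector or `grey_series`.
#' @return numeric vector of the same length.
#' @export
ago <- function(x) cumsum(as.numeric(as_grey_series(x)))

#' Inverse accumulated generating operation (first differences)
#'
#' @param x1 numeric vector of accumulated values.
#' @return the raw series whose cumulative sums equal `x1`.
#' @export
iago <- function(x1) {
  x1 <- as.numeric(x1)
  if (length(x1) < 1L) stop_grey("empty_series", "nothing to difference")
  c(x1[1L], diff(x1))
}

#' Membership-weighted background values
#'
#' The background value of the grey differential equation, generalised from
#' the conventional midpoint: \eqn{z^{(1)}(k) = x^{(1)}(k-1) + MF_k\,
#' x^{(0)}(k)} for \eqn{k = 2..n}. With all weights 1/2 this reduces exactly
#' to the classic GM(1,1) midpoint \eqn{(x^{(1)}(k-1) + x^{(1)}(k))/2};
#' larger weights push the background toward the newest accumulated value,
#' expressing the new-information-priority principle.
#'
#' @param x numeric vector or `grey_series` of length at least 2.
#' @param weights membership degrees in `[0, 1]`, one per observation.
#' @return numeric vector of `length(x) - 1` background values (k = 2..n).
#' @export
background_values <- function(x, weights) {
  x <- as.numeric(as_grey_series(x))
  n <- length(x)
  if (length(weights) != n) {
    stop_grey("length_mismatch", sprintf(
      "weights (%d) and series (%d) differ in length", length(weights), n))
  }
  if (n < 2L) stop_grey("insufficient_data", "need at least 2 observations")
  x1 <- cumsum(x)
  x1[seq_len(n - 1L)] + weights[-1L] * x[-1L]
}

#' Fit a fuzzy-weighted GM(1,1) grey model
#'
#' Fits the first-order one-variable grey model
#' \eqn{x^{(0)}(k) + a\,z^{(1)}(k) = b} by ordinary least squares on the
#' accumulated series, with background values \eqn{z^{(1)}(k)} weighted by
#' triangular membership degrees from the mega-trend-diffusion profile of the
#' fitting window (`background = "mtd"`, the default), by the conventional
#' midpoint weight 1/2 (`"classic"`), or by a fixed user weight (`"fixed"`).
#' The development coefficient `a` sets the exponential trend rate (a > 0
#' means decline) and the grey input `b` the level.
#'
#' The two-column least-squares system is solved by QR decomposition; the
#' solution agrees with the textbook normal equations
#' \eqn{\hat a = (B^T B)^{-1} B^T Y} on well-conditioned inputs.
#'
#' @param x numeric vector or `grey_series` with at least `min_n`
#'   non-negative observations.
#' @param background one of `"mtd"`, `"classic"`, `"fixed"`.
#' @param weight fixed background weight in `[0, 1]`; only for
#'   `background = "fixed"`.
#' @param lb_skew passed to [diffusion_bounds()] when `background = "mtd"`.
#' @param min_n minimum window length; 4 is the grey-modelling convention
#'   and can only be raised, not lowered.
#' @return An object of class `gm11`: list with coefficients `a` and `b`,
#'   the membership `weights`, `background` values \eqn{z^{(1)}(k)}, the
#'   accumulated series `ago`, the fitted `series`, and the time-response
#'   constants `c_scale` \eqn{= x^{(0)}(1) - b/a} and `c_offset` \eqn{= b/a}.
#' @examples
#' fit <- gm11(grey_series(c(24.681, 23.212, 22.144, 21.851), 2007:2010))
#' coef(fit)
#' predict(fit, h = 1)
#' @seealso [predict.gm11()], [time_response()], [gm_backtest()],
#'   [gm_rolling_forecast()]
#' @export
gm11 <- function(x, background = c("mtd", "classic", "fixed"), weight = 0.5,
                 lb_skew = c("sl", "su"), min_n = 4L) {
  background <- match.arg(background)
  lb_skew <- match.arg(lb_skew)
  series <- as_grey_series(x)
  n <- length(series)
  if (min_n < 4L) {
    stop_grey("bad_argument", "min_n below 4 is not supported")
  }
  if (n < min_n) {
    stop_grey("insufficient_data", sprintf(
      "grey modelling needs at least %d observations, got %d", min_n, n))
  }
  w <- switch(background,
    mtd = membership_values(series,
                            diffusion_bounds(series, lb_skew = lb_skew)),
    classic = rep(0.5, n),
    fixed = {
      if (length(weight) != 1L || is.na(weight) || weight < 0 || weight > 1) {
        stop_grey("bad_argument", "fixed weight must be a single value in [0, 1]")
      }
      rep(weight, n)
    })
  z <- background_values(series, w)
  if (max(z) == min(z)) {
    stop_grey("singular_system",
              "constant background values: least-squares system is singular")
  }
  B <- cbind(neg_z = -z, intercept = 1)
  Y <- as.numeric(series)[-1L]
  ab <- qr.coef(qr(B), Y)
  a <- unname(ab[1L]); b <- unname(ab[2L])
  if (!all(is.finite(c(a, b)))) {
    stop_grey("singular_system", "least-squares solution is not finite")
  }
  if (abs(a) < 1e-12) {
    stop_grey("near_zero_development", sprintf(
      "development coefficient a = %g is numerically zero; the exponential
time response is undefined", a))
  }
  structure(list(a = a, b = b, weights = w, background = z,
                 ago = cumsum(as.numeric(series)), series = series,
                 background_mode = background, lb_skew = lb_skew,
                 c_scale = as.numeric(series)[1L] - b / a,
                 c_offset = b / a),
            class = "gm11")
}

#' Grey time response
#'
#' The solution of the whitened differential equation with initial condition
#' \eqn{x^{(1)}(1) = x^{(0)}(1)}:
#' \deqn{\hat x^{(1)}(k+1) = \left(x^{(0)}(1) - b/a\right) e^{-ak} + b/a.}
#' `k = 0` returns the first observation exactly.
#'
#' @param fit a `gm11` object.
#' @param k non-negative integer step(s), vectorised.
#' @return predicted accumulated values \eqn{\hat x^{(1)}(k+1)}.
#' @export
time_response <- function(fit, k) {
  stopifnot(inherits(fit, "gm11"))
  if (any(k < 0)) stop_grey("bad_argument", "k must be non-negative")
  fit$c_scale * exp(-fit$a * k) + fit$c_offset
}

#' Forecast from a fitted grey model
#'
#' Raw-series forecasts by first-differencing the time response:
#' \eqn{\hat x^{(0)}(k+1) = \hat x^{(1)}(k+1) - \hat x^{(1)}(k)} for the `h`
#' steps after the fitting window. Successive forecasts form a geometric
#' sequence with ratio \eqn{e^{-a}}. A negative forecast is mathematically
#' possible for extreme inputs and is returned as-is with a warning.
#'
#' @param object a `gm11` object.
#' @param h forecast horizon (number of steps ahead), a positive integer.
#' @param ... unused.
#' @return numeric vector of `h` one- to `h`-step-ahead forecasts, named by
#'   period label.
#' @export
predict.gm11 <- function(object, h = 1L, ...) {
  if (length(h) != 1L || h < 1L) {
    stop_grey("bad_argument", "horizon h must be a positive integer")
  }
  n <- length(object$series)
  k <- n + seq_len(h) - 1L          # time response is indexed from k = 0
  out <- time_response(object, k) - time_response(object, k - 1L)
  if (any(out < 0)) {
    warning("negative forecast value(s) produced; returned unclamped")
  }
  stats::setNames(out, periods(object$series)[n] + seq_len(h))
}

#' One-step reconstructions over the fitting window
#'
#' @param object a `gm11` object.
#' @param ... unused.
#' @return fitted raw values \eqn{\hat x^{(0)}(k)} for k = 1..n (the first
#'   equals the first observation by the initial condition).
#' @export
fitted.gm11 <- function(object, ...) {
  n <- length(object$series)
  x1hat <- time_response(object, 0:(n - 1L))
  stats::setNames(iago(x1hat), periods(object$series))
}

#' @export
residuals.gm11 <- function(object, ...) {
  as.numeric(object$series) - fitted(object)
}

#' @export
coef.gm11 <- function(object, ...) c(a = object$a, b = object$b)

#' @export
print.gm11 <- function(x, digits = 5L, ...) {
  cat("fuzzy-weighted GM(1,1) grey model\n")
  cat(sprintf("  window: %d observations (%d-%d), background: %s\n",
              length(x$series), min(periods(x$series)),
              max(periods(x$series)), x$background_mode))
  cat(sprintf("  a (development) = %.*f\n  b (grey input)  = %.*f\n",
              digits, x$a, digits, x$b))
  cat(sprintf("  time response: x^(1)(k+1) = (%.*f) exp(%+.*f k) + %.*f\n",
              digits, x$c_scale, digits, -x$a, digits, x$c_offset))
  invisible(x)
}

#' @export
summary.gm11 <- function(object, ...) {
  res <- residuals(object)[-1L]     # first point is exact by construction
  structure(list(fit = object, residuals = res,
                 ape = abs(res) / as.numeric(object$series)[-1L]),
            class = "summary.gm11")
}

#' @export
print.summary.gm11 <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  membership weights: %s\n",
              paste(sprintf("%.4f", x$fit$weights), collapse = " ")))
  cat(sprintf("  in-window MAPE: %.2f%%\n", 100 * mean(x$ape)))
  invisible(x)
}

#' Plot a fitted grey model
#'
#' Observed values, one-step reconstructions over the window and, optionally,
#' forecasts beyond it.
#'
#' @param x a `gm11` object.
#' @param h forecast horizon to display (0 for none).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gm11 <- function(x, h = 0L, ...) {
  p <- periods(x$series)
  obs <- as.numeric(x$series)
  fit <- fitted(x)
  fc <- if (h > 0L) predict(x, h = h) else numeric(0)
  xs <- c(p, if (h > 0L) p[length(p)] + seq_len(h))
  graphics::plot(p, obs, type = "b", pch = 16, xlim = range(xs),
                 ylim = range(c(obs, fit, fc)),
                 xlab = "period", ylab = "value", ...)
  graphics::lines(p, fit, lty = 2, col = "grey40")
  if (h > 0L) {
    graphics::points(p[length(p)] + seq_len(h), fc, pch = 1, col = "red")
  }
  invisible(x)
}

#' Simulate series from a fitted grey model
#'
#' Draws `nsim` synthetic series from the fitted exponential dynamics via
#' [generate_series()], using the fitted coefficients and the window length
#' and first value of the fitting window.
#'
#' @param object a `gm11` object.
#' @param nsim number of series.
#' @param seed optional RNG seed.
#' @param noise_sd multiplicative Gaussian noise standard deviation.
#' @param ... unused.
#' @return a list of `grey_series` of length `nsim`.
#' @export
simulate.gm11 <- function(object, nsim = 1L, seed = NULL, noise_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$series)
  lapply(seq_len(nsim), function(i) {
    generate_series(a = object$a, b = object$b,
                    x1 = as.numeric(object$series)[1L], n = n,
                    noise_sd = noise_sd)
  })
}
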