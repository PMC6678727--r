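#' China's annual sulfur dioxide emissions, 2007-2015
#'
#' The case-study series: nine annual observations of China's sulfur dioxide
#' emissions in million tons, as published by the National Bureau of
#' Statistics of China. Also shipped as a CSV at
#' `system.file("extdata", "china_so2.csv", package = "greymtd")`.
#'
#' @return a `grey_series` of length 9 with periods 2007-2015.
#' @examples
#' china_so2()
#' @export
china_so2 <- function() {
  grey_series(c(24.681, 23.212, 22.144, 21.851, 22.179,
                21.176, 20.44, 19.744, 18.591),
              periods = 2007:2015)
}

#' Generate a synthetic grey-dynamics series
#'
#' Simulates a series following the grey exponential time response: the first
#' value is `x1` and subsequent values are the first differences of
#' \eqn{(x_1 - b/a)e^{-a(k-1)} + b/a}, optionally perturbed by multiplicative
#' Gaussian noise, value \eqn{\times (1 + \epsilon_k)} with
#' \eqn{\epsilon_k \sim N(0, noise\_sd^2)}. Multiplicative noise keeps small
#' perturbations positive and matches the relative-error metric (MAPE) used
#' to score forecasts. With `noise_sd = 0` the output is deterministic
#' regardless of seed.
#'
#' @param a development coefficient (nonzero; positive means decline).
#' @param b grey input coefficient.
#' @param x1 first value, positive.
#' @param n series length, at least 4.
#' @param noise_sd standard deviation of the multiplicative noise, >= 0.
#' @param seed optional integer seed for the noise.
#' @param periods period labels, defaulting to `1:n`.
#' @return a `grey_series` of length `n`.
#' @examples
#' generate_series(a = 0.05, b = 25, x1 = 24, n = 8)
#' @export
generate_series <- function(a, b, x1, n, noise_sd = 0, seed = NULL,
                            periods = seq_len(n)) {
  if (n < 4L) stop_grey("bad_argument", "n must be at least 4")
  if (x1 <= 0) stop_grey("bad_argument", "x1 must be positive")
  if (noise_sd < 0) stop_grey("bad_argument", "noise_sd must be non-negative")
  if (abs(a) < 1e-12) {
    stop_grey("near_zero_development", "a must be bounded away from zero")
  }
  x1hat <- (x1 - b / a) * exp(-a * (seq_len(n) - 1L)) + b / a
  vals <- iago(x1hat)               # exact: first element is x1
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals * (1 + stats::rnorm(n, 0, noise_sd))
  }
  if (any(vals < 0)) {
    stop_grey("negative_sample",
              "noise produced a negative value; use a smaller noise_sd")
  }
  grey_series(vals, periods = periods)
}
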