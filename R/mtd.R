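#' Central location of a sample
#'
#' The central location (CL) of the mega-trend-diffusion profile is the
#' midpoint of the sample extremes, \eqn{(\bar e + \underline e)/2}. It is the
#' apex of the triangular membership function.
#'
#' @param x numeric vector or `grey_series`.
#' @return the midpoint of `max(x)` and `min(x)`.
#' @export
central_location <- function(x) {
  x <- as.numeric(as_grey_series(x))
  (max(x) + min(x)) / 2
}

#' Skew counts and coefficients about the central location
#'
#' Counts the observations strictly above (`n_plus`) and strictly below
#' (`n_minus`) the central location, and forms the skew coefficients
#' \eqn{SU = N^+/(N^+ + N^-)} and \eqn{SL = N^-/(N^+ + N^-)}. Observations
#' exactly at the central location are counted in neither tail.
#'
#' @param x numeric vector or `grey_series`.
#' @param center central location; defaults to [central_location()] of `x`.
#' @return list with `n_plus`, `n_minus`, `skew_upper`, `skew_lower`.
#' @export
skew_profile <- function(x, center = central_location(x)) {
  x <- as.numeric(as_grey_series(x))
  n_plus <- sum(x > center)
  n_minus <- sum(x < center)
  if (n_plus + n_minus == 0L) {
    stop_grey("degenerate_data",
              "all observations equal the central location; skew undefined")
  }
  list(n_plus = n_plus, n_minus = n_minus,
       skew_upper = n_plus / (n_plus + n_minus),
       skew_lower = n_minus / (n_plus + n_minus))
}

#' Mega-trend-diffusion data profile
#'
#' Estimates the plausible data range of a small sample by skew-weighted
#' diffusion about the central location. The raw bounds are
#' \deqn{UB = CL + SU\sqrt{-2\,\hat s^2/N^+ \cdot \ln 10^{-20}}, \qquad
#'       LB = CL - SL\sqrt{-2\,\hat s^2/N^- \cdot \ln 10^{-20}},}
#' with \eqn{\hat s^2} the unbiased sample variance and \eqn{\ln 10^{-20}}
#' the fixed expansion coefficient. Each bound is then clamped outward so the
#' adjusted range always covers the observed extremes:
#' `ub_adj = max(ub_raw, max(x))`, `lb_adj = min(lb_raw, min(x))`.
#'
#' The lower-bound radical is weighted by the lower skew coefficient SL so
#' that diffusion widens on the side holding more mass. `lb_skew = "su"`
#' instead weights it by SU, an alternative sometimes seen in print; the
#' default is the form consistent with the original mega-trend-diffusion
#' technique.
#'
#' @param x numeric vector or `grey_series` with at least 2 distinct values.
#' @param lb_skew which skew coefficient multiplies the lower-bound radical:
#'   `"sl"` (default) or `"su"`.
#' @return An object of class `mtd_profile`: list with `center`, `n_plus`,
#'   `n_minus`, `skew_upper`, `skew_lower`, `variance`, `ub_raw`, `lb_raw`,
#'   `ub_adj`, `lb_adj`, `expansion`.
#' @examples
#' diffusion_bounds(c(24.681, 23.212, 22.144, 21.851))
#' @export
diffusion_bounds <- function(x, lb_skew = c("sl", "su")) {
  lb_skew <- match.arg(lb_skew)
  x <- as.numeric(as_grey_series(x))
  if (length(x) < 2L) {
    stop_grey("insufficient_data",
              "diffusion profile needs at least 2 observations")
  }
  if (max(x) == min(x)) {
    stop_grey("degenerate_data",
              "constant series: diffusion bounds are undefined")
  }
  center <- central_location(x)
  sk <- skew_profile(x, center)
  if (sk$n_plus == 0L || sk$n_minus == 0L) {
    stop_grey("degenerate_data",
              "no observations on one side of the central location")
  }
  s2 <- stats::var(x)
  expansion <- log(1e-20)
  ub_raw <- center + sk$skew_upper * sqrt(-2 * s2 / sk$n_plus * expansion)
  lb_coef <- if (lb_skew == "sl") sk$skew_lower else sk$skew_upper
  lb_raw <- center - lb_coef * sqrt(-2 * s2 / sk$n_minus * expansion)
  structure(c(list(center = center), sk,
              list(variance = s2, ub_raw = ub_raw, lb_raw = lb_raw,
                   ub_adj = max(ub_raw, max(x)), lb_adj = min(lb_raw, min(x)),
                   expansion = expansion, lb_skew = lb_skew)),
            class = "mtd_profile")
}

#' @export
print.mtd_profile <- function(x, ...) {
  cat("mega-trend-diffusion profile\n")
  cat(sprintf("  center (CL)     %.6g\n", x$center))
  cat(sprintf("  skew  N+ %d  N- %d   SU %.4g  SL %.4g\n",
              x$n_plus, x$n_minus, x$skew_upper, x$skew_lower))
  cat(sprintf("  variance        %.6g\n", x$variance))
  cat(sprintf("  bounds raw      [%.6g, %.6g]\n", x$lb_raw, x$ub_raw))
  cat(sprintf("  bounds adjusted [%.6g, %.6g]\n", x$lb_adj, x$ub_adj))
  invisible(x)
}

#' Triangular membership values of observations
#'
#' Evaluates the triangular membership function with apex at the central
#' location and feet at the adjusted diffusion bounds:
#' \deqn{MF(x_i) = \frac{x_i - LB_{adj}}{CL - LB_{adj}} \;(x_i \le CL), \qquad
#'       MF(x_i) = \frac{UB_{adj} - x_i}{UB_{adj} - CL} \;(x_i > CL).}
#' The value is 1 exactly at CL and 0 at either bound; every observation maps
#' into \eqn{[0, 1]} because the adjusted bounds cover the data.
#'
#' @param x numeric vector or `grey_series`.
#' @param profile an `mtd_profile` for `x`; defaults to [diffusion_bounds()].
#' @return numeric vector of membership degrees in `[0, 1]`, one per
#'   observation.
#' @examples
#' membership_values(c(24.681, 23.212, 22.144, 21.851))
#' @export
membership_values <- function(x, profile = diffusion_bounds(x)) {
  x <- as.numeric(x)   # MF is a function of position, evaluable anywhere
  cl <- profile$center
  if (profile$lb_adj >= cl || profile$ub_adj <= cl) {
    stop_grey("degenerate_data",
              "central location coincides with a diffusion bound")
  }
  ifelse(x <= cl,
         (x - profile$lb_adj) / (cl - profile$lb_adj),
         (profile$ub_adj - x) / (profile$ub_adj - cl))
}
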