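# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# Literal transcription of the mega-trend-diffusion profile equations,
# element by element, with the lower-bound radical weighted by SL.
oracle_mtd <- function(x) {
  emax <- max(x); emin <- min(x)
  cl <- (emax + emin) / 2
  np <- 0L; nm <- 0L
  for (v in x) {
    if (v > cl) np <- np + 1L
    if (v < cl) nm <- nm + 1L
  }
  su <- np / (np + nm); sl <- nm / (np + nm)
  xbar <- sum(x) / length(x)
  s2 <- sum((x - xbar)^2) / (length(x) - 1)
  ub <- cl + su * sqrt(-2 * s2 / np * log(10^-20))
  lb <- cl - sl * sqrt(-2 * s2 / nm * log(10^-20))
  ub_adj <- if (ub >= emax) ub else emax
  lb_adj <- if (lb <= emin) lb else emin
  mf <- vapply(x, function(v) {
    if (v <= cl) (v - lb_adj) / (cl - lb_adj)
    else (ub_adj - v) / (ub_adj - cl)
  }, numeric(1))
  list(cl = cl, np = np, nm = nm, su = su, sl = sl, s2 = s2,
       ub = ub, lb = lb, ub_adj = ub_adj, lb_adj = lb_adj, mf = mf)
}

# Two-parameter least squares via the explicit normal equations
# (B^T B)^{-1} B^T Y, solved in closed form.
oracle_ols <- function(z, y) {
  s_zz <- sum(z * z); s_z <- sum(z); s_zy <- sum(z * y); s_y <- sum(y)
  m <- length(z)
  det <- s_zz * m - s_z * s_z
  a <- -(m * s_zy - s_z * s_y) / det      # sign: design column is -z
  b <- (s_zz * s_y - s_z * s_zy) / det
  c(a = a, b = b)
}

# Random short positive series with both tails populated about the midpoint
# (so the diffusion profile is well defined).
random_series <- function(n = 6L) {
  repeat {
    x <- round(stats::runif(n, 1, 100), 3)
    cl <- (max(x) + min(x)) / 2
    if (any(x > cl) && any(x < cl) && max(x) > min(x)) return(x)
  }
}
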