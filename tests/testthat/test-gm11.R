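x4 <- c(24.681, 23.212, 22.144, 21.851)

test_that("AGO forms partial sums and IAGO inverts it exactly", {
  expect_equal(ago(x4), c(24.681, 47.893, 70.037, 91.888))
  expect_equal(ago(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(ago(5), 5)
  expect_equal(iago(ago(x4)), x4)
  expect_identical(iago(7), 7)
  set.seed(3)
  for (i in 1:20) {
    x <- random_series(sample(4:15, 1))
    expect_equal(iago(ago(x)), x)
  }
})

test_that("background values interpolate between accumulated neighbours", {
  mf <- c(0.5395, 0.9899, 0.7892, 0.7341)
  expect_equal(background_values(x4, mf), c(47.657, 65.369, 86.079),
               tolerance = 1e-4)
  # weight 1/2 recovers the conventional midpoint background
  x1 <- ago(x4)
  expect_equal(background_values(x4, rep(0.5, 4)),
               (x1[-4] + x1[-1]) / 2)
  # weight 1 lands on the newest accumulated value
  expect_equal(background_values(x4, rep(1, 4)), x1[-1])
  expect_error(background_values(x4, c(0.5, 0.5)),
               class = "greymtd_length_mismatch")
})

test_that("MTD-weighted fit reproduces the published coefficients", {
  fit <- gm11(x4)
  expect_equal(round(fit$a, 5), 0.03483)
  expect_equal(round(fit$b, 5), 24.71380)
  expect_equal(unname(coef(fit)), c(fit$a, fit$b))
})

test_that("fit agrees with the normal-equations oracle on random inputs", {
  set.seed(99)
  for (i in 1:30) {
    x <- random_series(sample(4:10, 1))
    fit <- gm11(x)
    o <- oracle_ols(fit$background, x[-1])
    expect_equal(fit$a, unname(o["a"]), tolerance = 1e-8)
    expect_equal(fit$b, unname(o["b"]), tolerance = 1e-8)
  }
})

test_that("classic mode equals the conventional midpoint GM(1,1)", {
  fit <- gm11(x4, background = "classic")
  x1 <- ago(x4)
  z_mid <- (x1[-4] + x1[-1]) / 2
  expect_equal(fit$background, z_mid)
  o <- oracle_ols(z_mid, x4[-1])
  expect_equal(fit$a, unname(o["a"]), tolerance = 1e-10)
  expect_equal(fit$b, unname(o["b"]), tolerance = 1e-10)
  # fixed weight 0.5 is the same model
  expect_equal(coef(gm11(x4, background = "fixed", weight = 0.5)), coef(fit))
  # the MTD weighting genuinely changes the fit on this series
  expect_gt(abs(gm11(x4)$a - fit$a), 1e-4)
})

test_that("time response honours the initial condition and its shape", {
  fit <- gm11(x4)
  expect_equal(fit$c_scale, -684.91656, tolerance = 1e-3)
  expect_equal(fit$c_offset, 709.59756, tolerance = 1e-3)
  expect_equal(time_response(fit, 0), x4[1])
  # a > 0: accumulated prediction rises concavely toward the asymptote b/a
  tr <- time_response(fit, 0:20)
  expect_true(all(diff(tr) > 0))
  expect_true(all(diff(diff(tr)) < 0))
  expect_true(all(tr < fit$c_offset))
})

test_that("forecasts difference the time response with geometric decay", {
  fit <- gm11(x4)
  expect_equal(unname(predict(fit, h = 1)), 21.118, tolerance = 1e-3)
  fc <- predict(fit, h = 6)
  expect_equal(unname(fc[-1] / fc[-6]), rep(exp(-fit$a), 5), tolerance = 1e-12)
  expect_true(all(diff(fc) < 0))           # a > 0 means decline
  expect_named(predict(gm11(grey_series(x4, 2007:2010)), h = 2),
               c("2011", "2012"))
})

test_that("fitted/residuals reconstruct the window one step at a time", {
  fit <- gm11(x4)
  f <- fitted(fit)
  expect_equal(unname(f[1]), x4[1])        # exact by the initial condition
  expect_equal(unname(residuals(fit)), x4 - unname(f))
})

test_that("noise-free grey dynamics are recovered by the fit", {
  # series generated exactly from the time response, fitted with the weights
  # that make the background consistent with the differential equation
  a_true <- 0.05; b_true <- 25
  x <- as.numeric(generate_series(a = a_true, b = b_true, x1 = 24, n = 8))
  x1 <- ago(x)
  # weights that reproduce the exact-solution background
  # z(k) = (x1(k) - x1(k-1) e^{-a}) ... instead check the classic fit is close
  fit <- gm11(x, background = "classic")
  expect_equal(fit$a, a_true, tolerance = 0.05 * a_true)
  # grey differential-equation residuals are near zero at the fitted optimum
  resid <- x[-1] + fit$a * fit$background - fit$b
  expect_lt(max(abs(resid)), 1e-2)
})

test_that("fit guards its preconditions with typed errors", {
  expect_error(gm11(c(1, 2, 3)), class = "greymtd_insufficient_data")
  expect_error(gm11(x4, min_n = 3), class = "greymtd_bad_argument")
  expect_error(gm11(rep(4, 6)), class = "greymtd_degenerate_data")
  # a constant series under classic weights fits a = 0 exactly
  expect_error(gm11(rep(4, 6), background = "classic"),
               class = "greymtd_near_zero_development")
  # constant background values make the normal equations singular
  expect_error(gm11(c(5, 0, 0, 0, 0), background = "fixed", weight = 0),
               class = "greymtd_singular_system")
  expect_error(gm11(x4, background = "fixed", weight = 1.5),
               class = "greymtd_bad_argument")
  expect_error(time_response(gm11(x4), -1), class = "greymtd_bad_argument")
})
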