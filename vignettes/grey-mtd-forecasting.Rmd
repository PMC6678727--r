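---
title: "Fuzzy-weighted grey forecasting for very short series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-weighted grey forecasting for very short series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greymtd)
```

## The problem

Annual environmental indicators — pollutant emissions being the motivating
case — often come as series of fewer than ten observations, and only the most
recent ones reflect current policy. Classical time-series machinery needs far
more data; what is wanted is a model that extracts a trend from as few as
four points. Grey system theory's GM(1,1) model is built for exactly this
regime, and `greymtd` implements a variant whose smoothing term adapts to the
shape of the sample through fuzzy membership weighting.

## The model

Let $x^{(0)} = \{x^{(0)}(1),\dots,x^{(0)}(n)\}$, $n \ge 4$, be a non-negative
series. The accumulated series $x^{(1)}(k) = \sum_{i\le k} x^{(0)}(i)$
smooths the raw data into a near-exponential curve, which GM(1,1) models by
the grey differential equation

$$x^{(0)}(k) + a\,z^{(1)}(k) = b,$$

where $z^{(1)}(k)$ is the *background value*, a smoothing point between
$x^{(1)}(k-1)$ and $x^{(1)}(k)$. The development coefficient $a$ sets the
exponential rate ($a>0$ is decline), the grey input $b$ the level. With the
initial condition $x^{(1)}(1)=x^{(0)}(1)$ the whitened equation has solution

$$\hat x^{(1)}(k+1) = \Big(x^{(0)}(1)-\tfrac{b}{a}\Big)e^{-ak}+\tfrac{b}{a},$$

and raw forecasts are its first differences, a geometric sequence with ratio
$e^{-a}$.

Conventionally $z^{(1)}(k)$ is the midpoint
$(x^{(1)}(k-1)+x^{(1)}(k))/2$, i.e. a fixed weight of $1/2$ on the newest
increment. `greymtd` instead sets

$$z^{(1)}(k) = x^{(1)}(k-1) + MF_k\,x^{(0)}(k),$$

where $MF_k \in [0,1]$ is a triangular fuzzy membership degree describing how
close observation $k$ lies to the centre of the sample's plausible range.
Observations near the centre of mass get weights near 1, pulling the
background toward the newest accumulated value and expressing the
new-information-priority principle of grey theory; outlying observations are
discounted toward the older value.

## The mega-trend-diffusion profile

The membership function is anchored by mega-trend diffusion (MTD), a
small-sample technique that estimates how far a population plausibly extends
beyond the observed extremes $\underline e = \min x$, $\bar e = \max x$:

* central location $CL = (\bar e + \underline e)/2$;
* skew counts $N^+$, $N^-$ of observations strictly above/below $CL$ (ties at
  $CL$ belong to neither tail), and coefficients $SU = N^+/(N^++N^-)$,
  $SL = N^-/(N^++N^-)$;
* unbiased sample variance $\hat s^2$;
* diffusion bounds
  $UB = CL + SU\sqrt{-2\hat s^2/N^+\cdot\ln 10^{-20}}$ and
  $LB = CL - SL\sqrt{-2\hat s^2/N^-\cdot\ln 10^{-20}}$.

The expansion coefficient is fixed at $\ln 10^{-20}$ — the conventional MTD
choice, exposed in the profile object but never silently altered. Each bound
is clamped *outward* so the adjusted range always covers the data:
$UB_{adj} = \max(UB, \bar e)$, $LB_{adj} = \min(LB, \underline e)$. The
membership of each observation is then the triangular function with apex 1 at
$CL$ and feet 0 at the adjusted bounds.

Two constructions deserve comment because variants circulate in print:

* **Lower-bound skew coefficient.** We weight the lower radical by $SL$, the
  proportion of mass below the centre, mirroring $SU$ above it; this is the
  form of the original MTD technique and the one under which the package
  reproduces the case-study coefficients below. A literal variant with $SU$
  in both radicals is available via `lb_skew = "su"`.
* **Clamp direction.** Both bounds clamp outward (toward wider ranges). A
  clamp that instead *replaced* a sufficiently wide formula bound with the
  sample extreme would defeat the stated purpose of avoiding insufficient
  expansion, and cannot reproduce the case-study fit; we use the symmetric
  outward clamp on both sides.

Degenerate samples (constant series, or all mass on one side of $CL$) leave
the diffusion undefined; the package raises typed errors
(`greymtd_degenerate_data`) rather than fabricating bounds.

## Estimation and numerical choices

Given the $n-1$ background values, $[a,b]^\top$ solves the two-column linear
least-squares system with rows $[-z^{(1)}(k),\,1] \cdot [a,b]^\top =
x^{(0)}(k)$. The solve uses QR decomposition; the test suite asserts
agreement with the explicit normal equations $(B^\top B)^{-1}B^\top Y$ to
$10^{-8}$ relative error on random inputs. No intermediate rounding happens
anywhere; five-decimal coefficient displays are presentation only.

Other numerical policies:

* $|a| < 10^{-12}$ raises `greymtd_near_zero_development` — the time response
  divides by $a$, and we prefer an explicit failure to a silent switch to a
  linear limit model.
* A constant background (possible for contrived inputs) raises
  `greymtd_singular_system`.
* The minimum window is 4 observations, the grey-modelling convention; it can
  be raised but not lowered.
* Negative forecasts are mathematically possible for extreme inputs and are
  returned unclamped with a warning.

## Backtesting and the rolling mechanism

Two deliberately distinct operations share the window machinery:

* `gm_backtest()` scores one-step-ahead accuracy: each window contains only
  *actual* observations and predicts the next actual. The MTD profile (and
  hence the weights) is recomputed for every window, since it depends on the
  window's extremes and variance.
* `gm_rolling_forecast()` produces medium-term forecasts beyond the data:
  after each one-step forecast the window is rolled forward by appending the
  forecast and dropping the oldest value, so from the second step on the
  windows are forecast-augmented. The `provenance` field records this.

Accuracy is summarised by MAPE, $\frac1m\sum|\hat y_i - y_i|/y_i$, stored as
a fraction and displayed in percent, and graded on the Lewis scale (<10%
highly accurate, 10–20% good, 20–50% reasonable, ≥50% inaccurate). The
printed cut points are read as half-open intervals $[10,20)$, $[20,50)$ —
the standard convention, putting each boundary in the weaker class.

## The case study

The bundled series `china_so2()` holds China's annual sulfur dioxide
emissions 2007–2015 in million tons. Fitting the 2007–2010 window:

```{r}
fit <- gm11(china_so2()[1:4])
fit
predict(fit, h = 1)
```

The five-window backtest over 2011–2015 and the rolling 2016–2020 forecast:

```{r}
gm_backtest(china_so2(), window = 4)
gm_rolling_forecast(china_so2(), window = 4, horizon = 5)
```

The rolling forecast's first window is taken as the four most recent actuals
(2012–2015): the rolling mechanism is defined by dropping the oldest value as
each new one arrives, and starting anywhere earlier would discard newer
actuals in favour of forecasts.

## The synthetic generator

`generate_series()` draws series that follow the grey dynamics exactly: first
value $x_1$, later values the first differences of
$(x_1 - b/a)e^{-a(k-1)} + b/a$, optionally perturbed by multiplicative
Gaussian noise $(1+\varepsilon_k)$, $\varepsilon_k \sim N(0, \sigma^2)$.
Multiplicative noise was chosen because it preserves positivity for small
$\sigma$ and matches the relative-error metric (MAPE) used for scoring; the
default is $\sigma = 0$ (exact dynamics). Property tests use $n = 8$,
$a = 0.05$ — a decline rate of the order seen in the case study — and noise
levels 0.005–0.03; at $\sigma = 0$ the fitted $a$ recovers the true rate
within 5%, and the recovery error grows with $\sigma$.

What the generator does *not* emulate: structural breaks, policy-driven
regime shifts, autocorrelated measurement error, or series whose trend is not
monotone-exponential. Passing tests on synthetic data therefore demonstrate
the estimator's correctness under the model's own assumptions, not
forecasting skill on arbitrary real series — the backtest on real data is the
evidence for the latter, and only for series of this general shape.

## Limitations

* The exponential time response cannot represent turning points; a series
  whose trend reverses inside the window will backtest poorly.
* With four-point windows the fit is exactly identified up to one residual
  degree of freedom; no meaningful standard errors exist, and the package
  reports none (nor prediction intervals).
* MAPE requires strictly positive actuals.
* The MTD profile needs observations on both sides of the central location;
  monotone windows always satisfy this, but e.g. a window with three equal
  values at one extreme does not.
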