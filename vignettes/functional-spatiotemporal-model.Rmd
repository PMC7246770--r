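---
title: "A functional dynamic spatio-temporal model for hourly pollutant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A functional dynamic spatio-temporal model for hourly pollutant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdstm)
```

## The model

Hourly readings from a pollutant monitoring network carry three kinds of
structure at once: a pronounced diurnal cycle within each day, day-to-day
dynamics, and spatial correlation across stations.  `fdstm` treats each
station-day of `q = 24` readings as one functional observation and models

$$
y(s,t,h) \;=\; x(s,t,h)'\beta(h) \;+\; \phi(h)' z(s,t) \;+\;
\varepsilon(s,t,h),
$$

where `s` indexes stations, `t = 1..T` days, and `h` the hour of day.  The
three ingredients:

* **Functional covariate effects.** Each effect curve is a Fourier expansion
  $\beta_j(h) = \phi_\beta(h)' c_{\beta,j}$ on the period-24 basis
  $(1, \sin\omega h, \cos\omega h, \sin 2\omega h, \dots)$,
  $\omega = 2\pi/24$, so hour 24 joins smoothly to hour 0 of the next day.
* **Latent spatio-temporal field.** $z(s,t) \in \mathbb{R}^{p}$ collects the
  basis coordinates of the latent daily profile at station `s`.  Component
  `j` follows an AR(1) in the day index with transition diagonal $g_j$
  ($|g_j| < 1$), and its innovations are spatially correlated with
  covariance $v_j \exp(-d(s,s')/\theta_j)$ — exponential in great-circle
  distance, scale $v_j$ in squared concentration units, range $\theta_j$ in
  km.  Components are independent of each other.
* **Heteroskedastic noise.** The measurement error is independent Gaussian
  with hour-varying variance $\log \sigma^2_\varepsilon(h) =
  \phi_\varepsilon(h)' c_\varepsilon$, which keeps the variance positive and
  smooth.

Stacked over stations and hours, a day is one observation vector of a
linear-Gaussian state space whose transition matrix is $G \otimes I_n$ and
whose innovation covariance is block-diagonal across latent components.  The
Kalman filter evaluates the exact observed-data likelihood (missing cells
are skipped — exact marginalization, not imputation), and the RTS smoother
supplies the conditional moments the EM algorithm needs.

The exponential correlation family is our choice: the model only requires a
valid correlation function on the sphere with one range parameter per
component, and the exponential kernel in great-circle distance is the
standard single-range choice in this model class.  Reported ranges are
family-dependent and should be read in that light.

## Estimation

`fit_em()` maximizes the likelihood by expectation–maximization:

* **E-step** — Kalman smoother at the current parameters; yields smoothed
  means, covariances and lag-one cross-covariances, hence the expected
  sufficient statistics and expected squared residuals per cell (for an
  unobserved cell this is the prediction variance
  $\phi(h)'P_t\phi(h) + \sigma^2_\varepsilon(h)$).
* **M-step** — conditional maximizations with guards:
  `c_beta` by weighted least squares against the latent-adjusted response
  (weights $1/\sigma^2_\varepsilon(h)$); `c_eps` by Newton steps on the
  hour-aggregated expected objective, which is strictly concave, with
  step-halving and a log-moment projection fallback; $g_j$ by the trace
  ratio $\mathrm{tr}(C_j^{-1}B_j)/\mathrm{tr}(C_j^{-1}A_j)$; $(v_j,
  \theta_j)$ by a bounded 1-D search over $\theta_j \in [1, 10^4]$ km with
  the scale profiled out in closed form, $v_j(\theta) =
  \mathrm{tr}(C(\theta)^{-1}M_j)/(nT)$.  Each update is compared with the
  previous value on the expected objective and kept only if it does not
  decrease it.

Because every update is a conditional maximization of the expected
complete-data objective, the observed-data log-likelihood trace is provably
non-decreasing (ECM); the test suite asserts this with slack `1e-8` and it
is the package's primary correctness sentinel alongside brute-force
joint-Gaussian oracles on tiny instances.

**Initial state.** The initial latent law is `N(0, S0)` with `S0` the
stationary covariance $v_j C(\theta_j)/(1-g_j^2)$ — the latent process has
no free initial parameters.  During one EM run `S0` is frozen at the
starting parameter value: this is what makes the M-step guards exact, and
with `T` in the dozens-to-hundreds the influence of one day's prior on the
fit is negligible.  Prediction and the information matrix use the stationary
law at the parameters they are given.

**Starting values** come from hour-wise ordinary least squares projected on
the bases, residual variances for `c_eps` (shifted down by `log 2` since
most residual structure belongs to the latent field), `g = 0.5`, `theta` at
the median inter-station distance, and the residual variance split equally
across components for `v`.

**Stopping.** Iteration ends when either the relative change of the
parameter vector or the relative change of the log-likelihood falls below
`tol` (default `1e-3`).  The default suits model comparison; note that the
parameter-vector norm is dominated by the large `v` scales, so effect
coefficients can still be moving at `1e-3`.  For parameter-recovery studies
compared against standard errors we therefore run with `tol = 1e-6`, and
the acceptance experiments do the same.

**Uncertainty.** `observed_information()` differentiates the marginal
log-likelihood numerically (central differences, step
$10^{-4}(1+|\psi_k|)$) in unconstrained coordinates — `atanh(g)`, `log(v)`,
`log(theta)`, raw basis coefficients — inverts the negative Hessian
(pseudo-inverse with a warning if necessary) and maps back by the delta
method.  Wald chi-square tests for a whole effect curve use the coefficient
block with degrees of freedom equal to the numerical rank (relative
singular-value tolerance `1e-10`).

## Model choice and validation

* `model_aic()` is the comparison criterion `logL - 2 npar`, maximized.
  `npar()` counts `p_eps + b * p_beta + 3 * p_z`; published counts for
  models of this family sometimes exclude the error-variance coefficients,
  so `include_c_eps = FALSE` reproduces that convention.
* `forward_select()` adds at each step the candidate covariate with the
  largest criterion; by default it emits the full path (stopping by
  inspection of the trace is common practice), with an optional
  relative-improvement threshold (0.1% is a reasonable default).
* `cv_two_fold()` and `loso_cv()` score held-out stations with
  $MSE_s$ over observed cells and $R^2_s = 1 - MSE_s/\mathrm{VAR}_s$;
  `basis_grid_search()` tabulates these plus the criterion over basis-size
  combinations.  The two-fold split defaults to seeded random halves.
* `predict_heldout()` is exact conditional-mean prediction: the latent
  state is augmented with the held-out locations (joint innovation
  covariance over all locations), the smoother reruns with held-out
  responses missing, and the prediction is $x'\hat\beta(h) + \phi(h)'
  \mathrm{E}[z|Y]$.  This is exact state augmentation, not plug-in kriging
  of smoothed states, and is testable against a brute-force Gaussian
  conditional mean.  Coincident locations are allowed; their latent values
  collapse onto the shared one (the smoother then works through a
  pseudo-inverse).

## The synthetic-data generator

`simulate_panel()` draws from exactly the generative model above, so every
pipeline stage is testable without any external data.  The default scenario
mirrors a dense summertime urban ozone study: 36 stations uniform in a
~50 km box (pairwise distances mostly under 60 km), 92 days of 24 hourly
readings, and a 7-component latent field with reference magnitudes
(`beijing_psi()`): one persistent component (`g = 0.739`) and faster minor
ones, ranges 31.9–63.1 km, scales averaging 2313 — i.e. roughly 48 units of
latent standard deviation, far above the measurement noise (defaults around
60–160 in variance).

Covariates are generated as smooth diurnal Fourier means plus station-level
AR(1) day-to-day perturbations plus white noise, with magnitudes loosely at
urban-pollutant scales; effect curves default to shapes of the kind seen in
ozone regressions (negative NO2-like curve, midday-peaking TEMP/UVB-like
curves, a sign-changing PM10-like curve, an exactly-zero IRAIN-like curve
useful as an inert control).  These are free choices recorded as the
simulation truth.  What the generator does *not* emulate: real atmospheric
chemistry (covariates are independent of the latent field and of each
other), instrument drift and calibration artefacts, and non-Gaussian tails.
Passing tests therefore demonstrate correctness of the machinery under the
model, not adequacy of the model for any particular real network.

## Numerical choices

* Within-day observations are processed sequentially (the noise covariance
  is diagonal), giving exact missing-data handling and an
  $O(m^2)$-per-observation filter; the covariance update is an in-place
  symmetric rank-one downdate with re-symmetrization each day.
* Great-circle distances use the haversine formula on a 6371 km sphere.
* `theta` searches are bounded to `[1, 1e4]` km and warn at the bounds;
  `g` updates are clamped to `(-0.9999, 0.9999)` (stationarity is checked,
  not enforced, at convergence).
* Hours sit at `h = 1..24` with period 24, so hour 24 wraps to hour 0 of
  the next day; the basis is left unnormalized (raw unit-amplitude sines
  and cosines) so latent scales keep interpretable squared-concentration
  units.
* Even basis-size requests are rejected rather than silently truncated; an
  explicit `allow_even = TRUE` escape hatch exists because the latent
  loading is occasionally wanted at an even dimension (the final harmonic
  pair is then truncated after its sine).

## Scale of the shipped experiments

The test suite and the acceptance script run everything on scaled-down
layouts — tiny instances (2–3 stations, 3–4 days) for exact oracle
comparisons, 6–12 stations and 40–200 days for EM, recovery, selection and
cross-validation studies.  These sizes were chosen as the smallest at which
the statistical claims are meaningful; the model itself has been exercised
at the full study layout (36 stations, 92 days, `p_z = 7`) and scales as
$O(T\,n\,q\,m^2)$ per likelihood evaluation with state dimension
$m = n\,p_z$.

## Known limitations

* The latent process has one draw per day; dependence across the day
  boundary at hour level is carried only through the day-level AR(1), which
  is the model as written.
* Information-matrix standard errors are asymptotic; with few stations the
  spatial parameters (`theta` especially) are weakly identified and their
  SEs can be optimistic.
* Forward selection refits the full model per candidate and step; with many
  candidates this is the dominant cost.
* No nugget in the spatial kernel: all small-scale variation is attributed
  to the heteroskedastic measurement error.
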