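---
title: "Trend models for crop-yield time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend models for crop-yield time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldtrends)
```

# The problem

Annual yield series from statistical agencies (FAOSTAT-style national
panels, AGRESTE-style sub-national panels) show three recurring shapes:
a strong rise that flattens into a plateau, a slow rise that
accelerates, and an approximately constant rate of increase. Two
questions drive the analysis: *which model predicts future yield best*,
and *what is the yearly yield-increase rate right now, with what
uncertainty*. This vignette records how the package answers both, and
why its numerical choices are what they are.

All models operate on the internal index $T = 1, \dots, M$ anchored at
each series' own first year; calendar years are metadata. Yields are in
t ha$^{-1}$, rates in t ha$^{-1}$ yr$^{-1}$, variances in t$^2$
ha$^{-2}$. Internal calendar gaps are kept as explicit missing
observations: regression models drop them, the Holt-Winters recursion
propagates its state along the trend without updating, and the Kalman
filter skips the measurement update. Agency panels rarely have such
gaps, so this is a generalisation, not a requirement of the data.

# The eight models

## Fixed-form regressions (L, Q, C, LP)

The polynomial trends
$Y_t = a + bT (+ cT^2)(+ dT^3) + \varepsilon_t$,
$\varepsilon_t \sim N(0, \sigma^2)$ i.i.d., are fitted by ordinary least
squares. Because their design matrices are nested, the in-sample RMSE
can only improve from L to Q to C; the test suite asserts this ordering
with $10^{-10}$ slack on every synthetic series. Residual
autocorrelations with the $\pm 1.96/\sqrt{M}$ white-noise band support
checking the independence assumption.

The linear-plus-plateau model
$$Y_t = a + R\,\min(T, T^*) + \varepsilon_t, \qquad
  Y_{\max} = a + R\,T^*$$
is continuous at the break by construction, which removes one redundant
parameter from the search. Fitting profiles the residual sum of squares
over every candidate integer break from the 3rd to the $(M\!-\!2)$th
observed point — conditional on $T^*$ the model is linear and solved
exactly — and then refines $T^*$ continuously around the best candidate
by one-dimensional profile-RSS optimisation.

**Why not a generic nonlinear least-squares refinement.** The RSS
surface has kinks in $T^*$ at every data point. Gauss-Newton aborts
with "singular gradient" on exactly-fitting data, and the `port`
variant declares "false convergence" on about a quarter of clean
plateau series. Profile optimisation cannot fail, so failure to
*converge* is replaced by failure to *identify*, which is the
scientifically meaningful event: a fit is reported `converged = FALSE`
when the refined break or its 95% confidence interval
($T^* \pm 1.96\,\mathrm{se}$, from the Gauss-Newton Jacobian at the
optimum) leaves the candidate window, or when that Jacobian is
numerically rank-deficient. On plateau-free series the apparent break
drifts to the end of the data with a wide interval, so these checks
reject it; on a seeded 50 + 50 panel the segmented fit is accepted on
100% of plateau-scenario units and 6–10% of linear-scenario units
(the residual acceptances are noise-induced genuine kinks). RMSEP is
not computed for LP: on truncated training sets the break date is
routinely unidentifiable, which is also why the model is excluded from
rolling-origin comparisons.

## Holt-Winters smoothing (HW0, HWs)

The trend variant updates level and slope as
$$\hat a_t = \alpha Y_t + (1-\alpha)(\hat a_{t-1} + \hat b_{t-1}),
\qquad
\hat b_t = \beta(\hat a_t - \hat a_{t-1}) + (1-\beta)\hat b_{t-1},$$
with forecast $\hat Y_{t+k} = \hat a_t + k \hat b_t$; the no-trend
variant (simple exponential smoothing) keeps only the level and
forecasts flat. Initialisation is the textbook convention
$\hat a_1 = Y_1$, $\hat b_1 = Y_2 - Y_1$ (slope divided by the gap
length if the second observation is not adjacent). On exactly linear
data this initialisation makes the recursion track the line exactly for
*any* $(\alpha, \beta)$, a property the tests verify by induction on
five constant pairs.

$(\alpha, \beta)$ minimise the in-sample sum of squared one-step
errors, accumulated from the third observation so the initialisation is
never rewarded. The objective is optimised on $[0,1]^2$ by bounded
L-BFGS-B from a 9-point grid of starts (the surface is flat near
$\alpha \to 0$, so multi-start is cheap insurance); the 1-D no-trend
problem uses golden-section search over three overlapping brackets plus
the interval endpoints. Optimised constants are only compared
structurally (grid dominance, limit behaviour), never against published
values: the exact initialisation used by any particular historical run
is not recoverable, and parameter values are not transferable across
initialisation conventions.

## Dynamic linear models (DLM0, DLMs)

The local linear trend model is
$$Y_t = L_t + \nu_t, \qquad
  L_t = L_{t-1} + b_{t-1} + w_{L,t}, \qquad
  b_t = b_{t-1} + w_{b,t},$$
with $\nu_t \sim N(0, \sigma^2_y)$, $w_{L,t} \sim N(0, \sigma^2_L)$,
$w_{b,t} \sim N(0, \sigma^2_b)$. The local level model drops the slope
($\sigma^2_b$ absent, forecasts flat). The slope $b_t$ *is* the yearly
yield-increase rate; everything the package reports about stagnation is
the smoothed $E[b_t \mid Y_{1:M}]$ with its posterior standard
deviation, quartiles ($\pm 0.67448975\,\mathrm{sd}$) and 95% bounds
($\pm 1.959964\,\mathrm{sd}$) — constants fixed numerically so output
is bit-stable across platforms. Smoothed, not filtered, quantities are
used for all reporting, because the scientific question is
retrospective trend reconstruction.

Numerical choices:

* **Prior.** Diffuse prior approximated by mean 0 and variance $10^7$
  per state component, the convention of the classical state-space
  packages; the first $d$ (state dimension) observed prediction-error
  terms are excluded from the log-likelihood so the prior's magnitude
  does not leak into inference. Exact-diffuse initialisation would be a
  refinement, not a correction.
* **Filter stability.** Covariance updates use the Joseph form; the
  smoother's one-step-ahead covariance inversion carries a
  $10^{-12}$-scale diagonal jitter so zero-disturbance limits (used in
  noiseless tests) stay well-posed. The smoothed variance is asserted
  $\le$ the filtered variance at every time point on every run.
* **Maximum likelihood.** The prediction-error-decomposition likelihood
  is optimised in log-variance coordinates (variances floored at
  $10^{-12}$) by Nelder-Mead from five method-of-moments starting
  points built from the variances of first and second differences;
  structural-model likelihoods are flat near zero variances, and the
  multi-start reliably escapes that shelf. The filter, smoother and
  likelihood kernels are C++ (via Rcpp), making a full MLE fit ~20 ms
  at $M = 50$, which is what keeps rolling-origin refits affordable.
* **Forecasts.** $k$-step means are $L + k b$ (trend) or $L$ (level);
  variances propagate the state covariance through $k$ system steps and
  add $\sigma^2_y$, verified against Monte-Carlo simulation.

The steady-state connection explains a robust empirical finding: for
fixed variances the local level filter gain converges to the constant
$\alpha$ solving $\alpha^2 = q(1-\alpha)$, $q = \sigma^2_L/\sigma^2_y$
(`steady_state_alpha()`), after which its one-step forecasts coincide
with simple exponential smoothing. Rolling RMSEPs of DLM0 and optimised
HW0 agree to a fraction of a percent on long series — the two are
interchangeable for prediction, while only the state-space side yields
retrospective trends and uncertainty.

# Validation against an independent oracle

The filter and smoother are validated against a brute-force
joint-Gaussian conditioning oracle that shares no code with the
recursions: the joint prior over all stacked states is written in
information (precision) form — block-tridiagonal for a Markov chain —
observations enter as rank-one information updates, and one solve gives
every conditional mean and variance. Agreement is required within
$10^{-8}$ absolute over 50 seeded series/specification pairs
($M \le 12$, both orders, random variances, priors and missing values);
measured agreement is ~$10^{-10}$. The covariance form of the same
oracle was abandoned: at prior variances ~50 it loses ~$10^{-8}$ to
cancellation, which would have tested the oracle's arithmetic rather
than the filter.

# Evaluation protocol

RMSE is the in-sample root mean square residual of the model fitted to
the full series (for the state-space models: against the smoothed
level; Holt-Winters models are forecast-only and get no RMSE). RMSEP at
horizon $k$ refits the model from scratch on all data up to $t - k$ for
each target year $t$ in the evaluation window (default: the final 20
years) and scores the $k$-step forecast; every forecast point records
the training-set end year so the protocol can be audited structurally
rather than trusted. Within one evaluation run, fits are cached by
(unit, model, origin) — the model refitted at a given origin is
identical whatever target/horizon pair requested it — but no estimation
state ever crosses origins. Panel aggregation is per-unit-then-average
(a pooled-error alternative is available via `aggregate = "pooled"`);
units where a model cannot be fitted are excluded from that model's
average and surface in `n_units`. Percent differences follow
$100\,(x - x_{\min})/x_{\min}$ within each statistic-horizon group.

The window convention resolves an ambiguity in agency-panel practice:
the package treats the window as a fixed set of target calendar years,
identical across horizons, with training ending at target $- k$; any
explicit window (e.g. `1991:2010`) can be passed.

Win-rate stratification (`dlms_vs_dlm0_winrate()`) compares the two
state-space models per unit at a horizon and splits units at the
across-unit median of the final-year smoothed rate; with an even unit
count the median is the lower central order statistic and at-median
units go to the low stratum, so neither stratum is ever empty.

# The synthetic generator as study design

`simulate_scenario_panel()` generates the panels every validation claim
is tested on, with fixed defaults chosen once to mirror published wheat
panels: calendar range 1961–2010 ($M = 50$); a plateau archetype
starting at 2.5 t ha$^{-1}$, rising 0.13 t ha$^{-1}$ yr$^{-1}$ to a
break in 1992 (≈ 6.5 t ha$^{-1}$ ceiling), observation noise sd 0.3; an
accelerating archetype from 0.5 to ≈ 3 t ha$^{-1}$ over the same span
(initial rate 0.02, rate growth 0.00127 yr$^{-2}$), noise sd 0.2; a
linear scenario at 0.05 t ha$^{-1}$ yr$^{-1}$, noise sd 0.25; and exact
state-space draws with $(\sigma^2_y, \sigma^2_L, \sigma^2_b) =
(0.09, 0.01, 10^{-4})$. Unit-level heterogeneity comes from lognormal
jitter (10% relative sd) on shape parameters and ±5 years on break
dates. Yields are floored at 0.05 t ha$^{-1}$ to respect positivity; a
configuration whose draws hit the floor more than 1% of the time is
rejected outright, because silent truncation would bias recovery tests.
Every simulation returns the latent truth alongside the observations,
in a separate table, so no pipeline stage can consume it by accident.

The parameter-recovery study runs the state-space draws from a start
level of 6 t ha$^{-1}$: over 60 years the slope random walk occasionally
(~1 in 100 replicates) wanders near −0.2 t ha$^{-1}$ yr$^{-1}$, which
from 2.5 t ha$^{-1}$ would cross the positivity floor and trigger the
rejection rule; starting higher keeps every replicate untruncated
without touching the floor logic.

What the generator does *not* emulate: autocorrelated observation
noise, heavy-tailed year effects (frost, drought), changes in variance
over time, cross-unit correlation from shared weather, and reporting
revisions. Passing tests therefore demonstrate correctness of the
estimators under the models' own assumptions and the qualitative
rankings among them — not that any model is adequate for a particular
real panel.

# Known limitations

* **Variance pile-up and band coverage.** At the recovery study's
  conditions ($M = 60$, $\sigma^2_b = 10^{-4}$) the maximum-likelihood
  estimate of the slope-disturbance variance collapses to the zero
  boundary in roughly a third of replicates — verifiably the global
  maximum (the profile likelihood is monotone to the boundary), not an
  optimiser artifact. Plug-in smoother bands are then too tight, and
  empirical 95%-band coverage of the true slope path is ~78% (94.7%
  when the true variances are plugged in). This is the well-known
  pile-up phenomenon of structural-model MLE at weak signal-to-noise;
  bands from short series should be read as lower bounds on
  uncertainty. A Bayesian treatment of the variances would widen them
  honestly but is out of scope.
* Medium-term median bias: with pile-up, the median $\hat\sigma^2_b$
  sits below truth (factor ~0.3–0.5 at these conditions), though within
  the factor-of-3 band the validation study requires.
* The LP identifiability rule is calibrated for yearly agronomic series
  lengths ($M \approx 40$–60); very short series leave too few
  candidate breaks for the profile to be informative.
* Forecast intervals for the regression and Holt-Winters models are not
  provided (point forecasts only), matching their role here as
  comparison baselines.

# Reproducibility

All randomness flows through R's Mersenne-Twister generator from
integer seeds recorded in every `simulation_config` and run manifest;
identical configuration and seed give bit-identical panels. The
validation suite (`tests/testthat/`) and the study script
(`scripts/acceptance.R`) regenerate everything they assert from those
seeds at run time. Problem sizes used by the study script — a 50-unit
mixed panel at horizons 1 and 10, 60 recovery replicates, a 500-point
steady-state series, 50 + 50 convergence-contrast units — were chosen
as the smallest sizes at which the qualitative conclusions are stable
across seeds.
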