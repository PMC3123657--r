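---
title: "Methods: joint competing-risks excess-hazard regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint competing-risks excess-hazard regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crexhaz)
```

## The model

`crexhaz` fits first-event (cause-specific) hazards for `J` competing
event types jointly. On the log scale, for event type `j`, time since
diagnosis `u`, and covariates `x`,

$$\eta_j(u, x) \;=\; s(u)'\gamma \;+\; b_j(u) \;+\; \sum_k (\alpha_k + \beta_{jk})\,x_k ,$$

with $b_1 \equiv 0$ and $\beta_{1k} \equiv 0$. The hazard of a
non-death event is $\exp(\eta_j)$; for the death stratum the *all-cause*
hazard is $\lambda_P(a+u, z) + \exp(\eta_j)$, where $\lambda_P$ is the
population (expected) mortality at the subject's attained age, calendar
year, and sex, taken from a life table and treated as known. The
modelled part of the death hazard is therefore an *excess* mortality
hazard: the mortality of event-free patients beyond what the general
population experiences.

Assumptions worth keeping in mind:

* **Random censoring** and a correctly specified life table. Errors in
  $\lambda_P$ propagate directly into the excess hazard.
* **Event-specific, not marginal, interpretation.** The latent-time
  construction in the simulator is a generating device; fitted hazard
  ratios compare event-specific hazards and say nothing about the
  hypothetical world in which competing events are abolished.
* **First events only.** Subsequent recurrences or death after
  recurrence are out of scope (no multi-state structure, no left
  truncation, no interval censoring).

## Time functions and degrees of freedom

Baseline log-hazards and between-event log hazard ratios $b_j(t)$ use
one of six functional families: constant, linear, quadratic, cubic, or
a cubic regression spline with one knot (default at 1 year) or two
knots (1 and 5 years). All bases include the constant, so the
dimensions are 1–6; in particular the one-knot cubic spline spans a
5-dimensional space, and comparing a constant $b_j$ to a spline
$b_j(t)$ is a 4-df likelihood-ratio test. The spline basis is a cubic
B-spline basis (`splines::bs` with an intercept): value, first and
second derivative are continuous at each interior knot.

Defaults and their rationale:

* **Interior knot at 1 year.** In many cancers a large share of events
  occurs during the first year after diagnosis. Users with different
  diseases should move it — e.g. to the median of the uncensored event
  times, which balances data support on both sides.
* **Boundary knots** default to `[0, max observed follow-up]`, resolved
  at fit time; evaluation outside them is an error, never a silent
  clamp. Specs with data-independent boundaries (as in the simulator)
  carry them explicitly.

## Estimation

### Data duplication and person-time banding

Each subject is duplicated once per event type, and each copy's
follow-up is split into bands. Cut points are a uniform monthly grid
(width `1/12` year, configurable), every attained-age and calendar-year
integer crossing of the subject, the spline knots, and the subject's
exit time. Because no band straddles an age/year boundary, $\lambda_P$
is a single number per band (evaluated at the band midpoint, where it
is constant by construction).

### Poisson-form likelihood

With one row per (subject, stratum, band), person-time $y$, event
indicator $d$ (1 only on the last band of the stratum matching the
observed event), the log-likelihood is

$$\ell(\theta) = \sum_{\text{bands}} d\,\log\tilde\lambda - y\, e^{\eta},
\qquad \tilde\lambda = \begin{cases} \lambda_P + e^{\eta} & \text{death stratum} \\ e^{\eta} & \text{otherwise.} \end{cases}$$

Two numerical choices matter:

* The exposure term $y\,e^\eta$ evaluates $\eta$ at the band midpoint —
  midpoint quadrature of the cumulative hazard, with error $O(w^2)$ in
  the band width $w$. The event term $d \log \tilde\lambda$ is evaluated
  at the *event time itself*, which makes it exact. (Evaluating the
  event term at the midpoint, as naive split-data fitting does, leaves a
  first-order error that visibly shifts the baseline intercept when the
  early hazard is steep; the package's tests verify that halving the
  band width moves coefficients by only a few times $10^{-3}$.)
* The term $-\sum y\,\lambda_P$ does not involve $\theta$ and is
  dropped. Log-likelihoods are therefore comparable across models
  fitted to the same bands (LR tests, AIC), but not across packages
  without adding the constant back.

### Optimisation

Newton–Raphson with the analytic gradient and Hessian. The death
stratum's $d\,\log(\lambda_P + e^\eta)$ is *convex* in $\eta$, so the
likelihood is not globally concave: the negative Hessian is
Cholesky-checked and ridge-regularised when needed, and every step is
step-halved until the log-likelihood does not decrease. Starting
values: a constant-hazard fit per stratum (events over person-time,
with the expected deaths subtracted on the death stratum, floored at
half an event), zero covariate effects. Convergence requires a relative
log-likelihood change below `1e-8` *and* maximum score below `1e-6`
(both configurable); the covariance is the inverse observed information
at the optimum and is withheld (with `converged = FALSE`) if the
information is singular. Linear-predictor overflow makes the likelihood
non-finite and is reported as an error rather than clipped; clipping is
applied nowhere in estimation.

When the true excess hazard is (near) zero the excess linear predictor
drifts to $-\infty$ with a vanishing gradient; the fit then converges
with a very negative coefficient and a large standard error. This is
the correct degenerate behaviour: on the natural scale the
confidence interval for the excess-hazard curve covers zero
(`predict_hazard(..., ci_scale = "natural")`), which is the scale on
which "no excess mortality" should be read. The default log-scale
interval is appropriate for curves bounded away from zero.

## Inference

Wald tests use the quadratic form on the observed-information
covariance; LR tests use twice the log-likelihood difference of nested
fits on the same bands with df equal to the parameter-count difference.
Hazard-ratio confidence intervals are normal-theory on the log scale,
using the joint covariance of $(\hat\alpha_k, \hat\beta_{jk})$. For
common-versus-differential effect questions the LR test is the primary
tool (1 df per binary/continuous covariate, 2 df for a three-level
factor); Wald tests are available for the same hypotheses. AIC
comparisons use $-2\ell + 2p$ with ties broken toward fewer parameters.

## The three-step strategy

1. **Pattern detection.** A proportional-hazards partial-likelihood fit
   (Breslow ties) on the duplicated data with event-type dummies;
   scaled Schoenfeld residuals of the dummies, a 20%-window running
   mean, and a least-squares trend with its 95% CI. This output is
   advisory — the formal decision between constant and time-dependent
   $b_j$ is the 4-df LR test, which `run_strategy()` performs for every
   non-reference event.
2. **Baseline selection.** Single-event fits (other events censored) of
   the six candidate time functions, ranked by AIC.
3. **Joint fit** with the selected forms, event-specific effects imposed
   on death, and per-covariate(-group) LR tests of common versus
   differential effects on the non-death events.

## The simulator and what it does (not) emulate

`simulate_cohort()` draws covariates, then one latent time per event
type by inverting its cumulative hazard on a fine grid (step `1/96`
year; hazards are treated as constant within grid cells, making the
inversion exact for the discretised hazard). The death event uses the
all-cause hazard $\lambda_P(a+t) + \text{excess}$, with $\lambda_P$
accumulated along each subject's attained-age path. The observed record
is the earliest latent time, truncated by exponential drop-out
censoring (rate calibrated by `calibrate_dropout()` so the *expected*
drop-out share over a 20 000-subject pilot matches the target within
Monte-Carlo error) and administrative censoring at the horizon.

Emulated features: three competing first events including excess
death; realistic adult expected mortality (synthetic Gompertz-type life
table, sex-specific, mild calendar drift); balanced binary and
standardised continuous prognostic factors; 7-year administrative
censoring; 0–30% drop-out. Not emulated: covariate-dependent or
informative censoring, left truncation/delayed entry, fractional ages
at diagnosis (the simulator rounds ages to whole years; the fitting
machinery itself handles fractional ages), multiple diagnosis years,
non-proportional covariate effects, and correlation between latent
event times. Passing tests therefore validate the estimator under a
clean randomized-censoring regime, not robustness to those violations.

## Reference scenario of the performance study

The truth used by `default_scenario()`:

* baseline: $\log\lambda_1$ = one-knot spline with coefficients
  `(-2.99, -2.13, -2.40, -3.14, -2.93)` — the projection of
  $\log(0.05 + 0.06\,t\,e^{1-t})$, a unimodal hazard rising to about
  0.11/year near one year and easing back to about 0.05/year;
* $b_2 = 0.45$ constant (the metastasis-like event's hazard is about
  1.6 times the recurrence baseline at all times);
* $b_3(t)$ = one-knot spline with coefficients
  `(1.13, -0.36, -0.73, -0.46, -0.57)` — the projection of
  $1.7 e^{-3t} - 0.55$: a high early excess (post-operative mortality)
  falling within the first half-year to a persistent level of roughly
  half the reference baseline. A late excess pinned at zero was
  deliberately avoided: it makes the death-stratum information matrix
  nearly singular under heavy drop-out, and a moderate persistent
  excess is what stage-III colon-type cohorts actually show;
* covariate effects $\alpha = (-0.4, 0.5, 0.3)$ on (binary sex, a
  binary factor, standardised age), with death-specific departures
  $\beta_{3} = (0.8, \cdot, 0.6)$ — all $|\log HR| \le 1.5$;
* ages `round(N(65, 9))` truncated to 40–86, diagnosis year 1995,
  horizon 7 years, N = 1000.

**Which parameters the study summarises.** Relative bias and empirical
coverage are reported per coefficient, but the headline maxima/minima
are taken over the *hazard-ratio parameters* — $\alpha_k$,
$\beta_{jk}$, and constant $b_j$ — the directly interpretable scalars
(`param_class()` tags them). Individual spline coefficients are
excluded from the headline on identification grounds: within a B-spline
basis they are strongly collinear, and the late coefficients of the
excess-death ratio are informed only by the (small) late excess over
$\lambda_P$, giving standard errors of order 1 and larger at N = 1000.
Their relative bias is then dominated by Monte-Carlo noise at any
feasible replicate count and measures nothing about the estimator;
curve recovery is instead checked at the functional level (fitted
log-hazard curves and time-dependent-ratio bands), where the
anticorrelated coefficients combine into well-identified values.

Truth magnitudes were fixed once, before the harness was run, under a
pre-registered noise rule: every headline parameter must satisfy
$se(\hat\theta)/(\sqrt{R}\,|\theta|) \lesssim 0.02$ at $R = 200$
replicates, so that an observed |relative bias| of a few percent
reflects bias, not simulation noise (pilot standard errors: the maximum
over headline parameters is about 0.02 even at 30% drop-out).

**Study sizes.** `scripts/acceptance.R` runs 300 replicates of N = 1000
per drop-out rate (0%, 15%, 30%); the test suite runs a pooled 100
replicates per rate. These sizes put the binomial standard error of a
per-parameter coverage estimate at about 1.1–1.5 percentage points.

## Degenerate inputs and tie-breaks

* Strata with zero observed events start from half an event in the
  initialiser and are estimable only through shared parameters.
* Duplicate band cut points within `1e-8` years are merged; subject
  exit times always survive the merge.
* `apply_exclusions()` counts unknown-stage records first; metastatic
  codes are counted among the remainder, so the two counts are
  disjoint.
* AIC ties rank the smaller model first.
* Per-replicate seeds are derived from the master seed as
  `(seed + 99991 r) mod (2^31 - 1)`; dropout calibration uses its own
  fixed pilot seed so it never perturbs the replicate stream.

## Known limitations

* No penalised splines or automatic knot search; the six candidate
  forms are the menu.
* No time-dependent covariate effects (the design extends naturally —
  interact a covariate with a time basis — but it is not implemented).
* No subdistribution-hazard (cumulative-incidence regression)
  quantities; cumulative incidences can be computed from the fitted
  hazards but no helper is provided.
* The banded likelihood's accuracy is governed by the band width;
  monthly bands are adequate for hazards on the scale of cancer-registry
  data, but hazards with sub-monthly structure need narrower bands.
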