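# crexhaz — joint competing-risks and excess-hazard regression

`crexhaz` is for population-based time-to-event studies (typically cancer
registries) in which a patient's first event can be one of several
competing types — say local recurrence, distant metastasis, or death —
and in which death is recorded *without* a reliable cause. In that
setting the all-cause death hazard mixes two components: the mortality
any person of the same age, sex, and calendar period would experience
(the *expected* or population hazard, known from national life tables),
and the *excess* mortality attributable, directly or indirectly, to the
disease. `crexhaz` estimates all event-specific hazards jointly, with
the death hazard decomposed additively into those two parts, so the
excess mortality of recurrence-free patients can be read off directly.

## The model

For event types `j = 1, …, J` (death denoted `E`, say), time since
diagnosis `t`, age at diagnosis `a`, and covariates `x`, the
event-specific hazards are

    λ_j(t, x)      = λ₁(t) · exp( b_j(t) + Σ_k (α_k + β_jk) x_k ),   j ≠ E
    λ_E(t, a, x, z) = λ_P(a + t, z) + λ₁(t) · exp( b_E(t) + Σ_k (α_k + β_Ek) x_k )

with `b₁ ≡ 0` and `β_1k ≡ 0` for identifiability. Here

* `log λ₁(t)` — the log baseline hazard of the reference event — is a
  cubic regression spline (default: one interior knot at 1 year);
* `b_j(t)` is the log hazard ratio between event `j`'s baseline and the
  reference baseline: a constant gives proportional baselines, a
  one-knot cubic spline gives a time-dependent ratio (5 df, so the
  constant-vs-spline likelihood-ratio test has 4 df);
* `α_k` is a covariate effect *common* to all event types and `β_jk` an
  event-specific departure, so `H₀: β_jk = 0` tests directly whether a
  covariate acts equally on two events, and the fitted hazard ratios are
  `exp(α_k)` and `exp(α_k + β_jk)`;
* `λ_P` is the expected mortality from a life table, treated as known.

Estimation duplicates each subject across the `J` event types and
splits follow-up into fine person-time bands (monthly by default, plus
every attained-age/year crossing so `λ_P` is constant within a band).
The full likelihood then becomes a sum of Poisson-form terms which is
maximised by Newton–Raphson with analytic derivatives; the
`d·log(λ_P + e^η)` term of the death stratum is handled exactly.

## Worked example

A synthetic registry extract (1016 records, of which 45 with unknown
stage and 35 metastatic at diagnosis) is generated, filtered, and
analysed with the three-step strategy: (1) Schoenfeld-residual patterns
and 4-df LR tests decide which between-event ratios are time-dependent,
(2) AIC picks the baseline time function among six candidates,
(3) the joint model is fitted and common-vs-differential covariate
effects are tested.

```r
library(crexhaz)
lt  <- make_lifetable()                      # synthetic national life table
raw <- simulate_registry_cohort(n = 1016, n_unknown_stage = 45,
                                n_stage4 = 35, seed = 7)
excl <- apply_exclusions(raw)
excl$counts
#>          unknown_stage synchronous_metastasis
#>                     45                     35
cohort <- excl$data                          # 936 analysable cases
res <- run_strategy(cohort, lt, J = 3,
                    groups = list(stage = c("stageII", "stageIII")))
res
#> Three-step joint excess-hazard analysis
#> step 1 - time dependence of between-event hazard ratios:
#>   b2_time_dependence: LR = 2.33 on 4 df, p = 0.675
#>   b3_time_dependence: LR = 18.53 on 4 df, p = 0.000972
#>   chosen forms: 2=constant, 3=cubic_spline
#> step 2 - baseline selection: winner spline_2knots
#> step 3 - joint fit:
#> Joint competing-risks excess-hazard fit (3 event types)
#>   936 subjects, 2405.2 person-years, events: 182 / 332 / 288
#>   logLik -2314.545 on 22 parameters, AIC 4673.09, converged in 6 iterations
#>   common-vs-differential stage: LR = 1.62 on 2 df, p = 0.445
#>   common-vs-differential sexf: LR = 0.42 on 1 df, p = 0.515
#>   ...
```

The ratio of metastasis to recurrence baselines is time-constant
(p = 0.68) while the excess-death ratio is clearly time-dependent
(p < 0.001), matching the generating model (the simulator's excess
death hazard starts high — post-operative mortality — and falls off
within the first year). Hazard ratios combine the common effect and the
event-specific departure; e.g. for sex:

```r
subset(res$step3$hazard_ratios, covariate == "sexf")
#>   covariate stratum     log_hr         se        hr     lower     upper
#> 1      sexf       1 -0.3865329 0.08950022 0.6794084 0.5700962 0.8096804
#> 2      sexf       2 -0.3865329 0.08950022 0.6794084 0.5700962 0.8096804
#> 3      sexf       3  0.4139976 0.14259528 1.5128535 1.1439829 2.0006642
```

and the fitted time-dependent excess-death/recurrence hazard ratio
`exp(b̂₃(t))` with its pointwise 95% band:

```r
time_dependent_hr(res$step3$fit, 3, c(0.1, 0.5, 1, 3, 6))
#>   time    hr lower upper se_log
#> 1  0.1 2.284 1.301 4.009  0.287
#> 2  0.5 1.257 0.776 2.035  0.246
#> 3  1.0 0.829 0.528 1.303  0.230
#> 4  3.0 0.700 0.421 1.162  0.259
#> 5  6.0 0.778 0.345 1.758  0.416
```

A command-line wrapper with `fit`, `simulate`, `validate`, and
`strategy` subcommands is installed under
`system.file("cli", "crexhaz.R", package = "crexhaz")`.

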