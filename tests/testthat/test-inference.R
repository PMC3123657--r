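fit_small_joint <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    sc <- default_scenario(n = 500)
    coh <- simulate_cohort(sc, seed = 23)
    b <- duplicate_and_band(coh, 3, sc$lifetable, cut_times = 1)
    memo <<- fit_crexhaz(truth_spec(sc), b)
    memo
  }
})

test_that("hazard ratios combine common and differential effects", {
  fit <- fit_small_joint()
  # x2 has only a common effect: identical HR on every event type
  hrs <- do.call(rbind, lapply(1:3, function(j) hazard_ratio(fit, "x2", j)))
  expect_equal(hrs$hr, rep(exp(coef(fit)["alpha:x2"]), 3),
               ignore_attr = TRUE)
  # reference event: HR = exp(alpha) even for covariates with departures
  hr1 <- hazard_ratio(fit, "sexf", 1)
  expect_equal(hr1$log_hr, unname(coef(fit)["alpha:sexf"]))
  # death event: alpha + beta with the joint covariance
  hr3 <- hazard_ratio(fit, "sexf", 3)
  expect_equal(hr3$log_hr,
               unname(sum(coef(fit)[c("alpha:sexf", "beta3:sexf")])))
  idx <- c("alpha:sexf", "beta3:sexf")
  expect_equal(hr3$se, sqrt(sum(vcov(fit)[idx, idx])))
  expect_error(hazard_ratio(fit, "nope", 1), "not in the model")
})

test_that("delta-method HR interval matches a parametric bootstrap", {
  fit <- fit_small_joint()
  hr3 <- hazard_ratio(fit, "sexf", 3)
  set.seed(99)
  idx <- c("alpha:sexf", "beta3:sexf")
  V <- vcov(fit)[idx, idx]
  ch <- chol(V)
  draws <- matrix(rnorm(2 * 2000), 2000) %*% ch
  boot <- rowSums(draws) + sum(coef(fit)[idx])
  # Gaussian draws from the fitted covariance: quantiles should agree
  # with the delta CI up to Monte-Carlo error
  q <- unname(quantile(boot, c(0.025, 0.975)))
  mc <- 3 * sd(boot) / sqrt(2000 * 0.025)
  expect_lt(abs(exp(q[1]) - hr3$lower), mc)
  expect_lt(abs(exp(q[2]) - hr3$upper), mc)
})

test_that("LR test bookkeeping: 4 df for time dependence, 2 df for a
           3-level factor, 0 for identical fits", {
  sc <- default_scenario(n = 300)
  coh <- simulate_cohort(sc, seed = 41)
  b <- duplicate_and_band(coh, 3, sc$lifetable, cut_times = 1)
  base <- time_spec("cubic_spline", knots = 1)
  m3 <- model_spec(3, 3, base, list("2" = time_spec("constant"),
                                    "3" = time_spec("constant")))
  m4 <- model_spec(3, 3, base, list("2" = time_spec("constant"),
                                    "3" = time_spec("cubic_spline", knots = 1)))
  f3 <- fit_crexhaz(m3, b); f4 <- fit_crexhaz(m4, b)
  tt <- lr_test(f3, f4)
  expect_equal(tt$df, 4L)
  expect_gte(tt$statistic, 0)
  expect_equal(tt$p_value, pchisq(tt$statistic, 4, lower.tail = FALSE))
  # identical fits: statistic 0, p = 1 (guard df via a 1-param extension)
  expect_error(lr_test(f4, f4), "more parameters")
  f4b <- fit_crexhaz(m4, b, crexhaz_control(init = coef(f4)))
  expect_equal(2 * (f4b$loglik - f4$loglik), 0, tolerance = 1e-6)

  # 3-level stage-like factor: common vs event-specific effect on two
  # non-death events = 2 df
  raw <- simulate_registry_cohort(600, 0, 0, seed = 5)
  coh2 <- apply_exclusions(raw)$data
  lt <- make_lifetable()
  b2 <- duplicate_and_band(coh2, 3, lt, cut_times = 1)
  covs_common <- list(stageII = covariate_effect(TRUE, 3),
                      stageIII = covariate_effect(TRUE, 3))
  covs_diff <- list(stageII = covariate_effect(TRUE, c(2, 3)),
                    stageIII = covariate_effect(TRUE, c(2, 3)))
  bj <- list("2" = time_spec("constant"), "3" = time_spec("constant"))
  fc <- fit_crexhaz(model_spec(3, 3, base, bj, covs_common), b2)
  fd <- fit_crexhaz(model_spec(3, 3, base, bj, covs_diff), b2)
  expect_equal(lr_test(fc, fd)$df, 2L)
})

test_that("Wald tests reduce to squared z on one parameter and reject
           degenerate contrasts", {
  fit <- fit_small_joint()
  w <- wald_test(fit, "beta3:sexf")
  est <- coef(fit)["beta3:sexf"]
  se <- sqrt(vcov(fit)["beta3:sexf", "beta3:sexf"])
  expect_equal(w$statistic, unname((est / se)^2))
  expect_equal(w$df, 1L)
  expect_error(wald_test(fit, matrix(0, 1, fit$n_params)), "zero")
  # scaling a covariate rescales the coefficient but not the Wald statistic
  sc <- quick_scenario(n = 400)
  coh <- simulate_cohort(sc, seed = 3)
  coh2 <- as.data.frame(coh); coh2$x2 <- coh2$x2 * 10
  coh2 <- as_cohort(coh2, attr(coh, "covariates"))
  spec <- truth_spec(sc)
  f1 <- fit_crexhaz(spec, duplicate_and_band(coh, 2, width = 1 / 12))
  f2 <- fit_crexhaz(spec, duplicate_and_band(coh2, 2, width = 1 / 12))
  expect_equal(wald_test(f1, "alpha:x2")$statistic,
               wald_test(f2, "alpha:x2")$statistic, tolerance = 1e-6)
  expect_equal(coef(f1)["alpha:x2"], 10 * coef(f2)["alpha:x2"],
               tolerance = 1e-6)
})

test_that("Wald and LR p-values agree asymptotically", {
  sc <- default_scenario(n = 5000)
  coh <- simulate_cohort(sc, seed = 77)
  b <- duplicate_and_band(coh, 3, sc$lifetable, cut_times = 1)
  spec_alt <- truth_spec(sc)
  fit_alt <- fit_crexhaz(spec_alt, b)
  # H0: beta3:sexf = 0
  covs0 <- spec_alt$covariates
  covs0$sexf <- covariate_effect(TRUE)
  spec0 <- model_spec(3, 3, spec_alt$baseline, spec_alt$bj, covs0)
  fit0 <- fit_crexhaz(spec0, b)
  p_lr <- lr_test(fit0, fit_alt)$p_value
  p_w <- wald_test(fit_alt, "beta3:sexf")$p_value
  expect_lt(abs(p_lr - p_w), 0.02)
})

test_that("LR statistics are invariant to band refinement", {
  sc <- default_scenario(n = 300)
  coh <- simulate_cohort(sc, seed = 19)
  stat_at <- function(w) {
    b <- duplicate_and_band(coh, 3, sc$lifetable, width = w, cut_times = 1)
    base <- time_spec("cubic_spline", knots = 1)
    m3 <- model_spec(3, 3, base, list("2" = time_spec("constant"),
                                      "3" = time_spec("constant")))
    lr_test(fit_crexhaz(m3, b), fit_crexhaz(truth_spec(sc), b))$statistic
  }
  expect_equal(stat_at(1 / 12), stat_at(1 / 24), tolerance = 0.02)
})

test_that("time-dependent HR curves are definitionally consistent", {
  fit <- fit_small_joint()
  tt <- c(0.5, 1.5, 4)
  # constant b_2: flat curve at exp(b2)
  c2 <- time_dependent_hr(fit, 2, tt)
  expect_equal(c2$hr, rep(unname(exp(coef(fit)["b2"])), 3))
  expect_equal(c2$se_log,
               rep(sqrt(vcov(fit)["b2", "b2"]), 3))
  # reference event: flat at 1
  expect_equal(time_dependent_hr(fit, 1, tt)$hr, rep(1, 3))
  # identity with the ratio of predicted hazards at x = 0
  c3 <- time_dependent_hr(fit, 3, tt)
  expect_equal(c3$hr,
               predict_hazard(fit, 3, tt)$hazard /
                 predict_hazard(fit, 1, tt)$hazard,
               tolerance = 1e-10)
})

test_that("AIC ranking is internally consistent", {
  fit <- fit_small_joint()
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(AIC(fit), fit$aic)
  tab1 <- aic_compare(list(only = fit))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$delta_aic, 0)
})
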