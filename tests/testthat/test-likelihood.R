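test_that("linear predictor honours the identifiability constraints", {
  spec <- model_spec(3, 3,
                     baseline = time_spec("cubic_spline", knots = 1,
                                          boundary = c(0, 7)),
                     bj = list("2" = time_spec("constant"),
                               "3" = time_spec("constant")),
                     covariates = list(x1 = covariate_effect(TRUE, 3)))
  theta <- c(-3, -2.5, -2.8, -3.2, -3, 0.6, 0.2, 0.4, 0.3)
  tt <- c(0.5, 2, 5)
  # reference event at x = 0: spline-only value
  B <- build_basis(spec$baseline, tt)
  expect_equal(linear_predictor(spec, theta, 1, tt), drop(B %*% theta[1:5]))
  # constant b_2: reference value plus b_2
  expect_equal(linear_predictor(spec, theta, 2, tt),
               linear_predictor(spec, theta, 1, tt) + 0.6)
  # covariate with common + differential effect on the death stratum
  expect_equal(linear_predictor(spec, theta, 3, tt, c(x1 = 1)) -
                 linear_predictor(spec, theta, 3, tt, c(x1 = 0)),
               rep(0.4 + 0.3, 3))
  # theta = 0: hazard 1 per person-year on every stratum
  expect_equal(linear_predictor(spec, numeric(9), 2, tt, c(x1 = 1)), rep(0, 3))
})

test_that("constant-hazard likelihood is maximised at events over person-time", {
  coh <- exp_cohort(150, hazards = 0.1, seed = 2)
  b <- duplicate_and_band(coh, 1, width = 1 / 12)
  spec <- model_spec(1, 1, baseline = time_spec("constant", boundary = c(0, 7)))
  D <- sum(coh$status); Y <- sum(coh$time)
  fit <- fit_crexhaz(spec, b)
  expect_true(fit$converged)
  expect_equal(unname(exp(coef(fit))), D / Y, tolerance = 1e-9)
  # the closed-form optimum beats nearby values
  ll_hat <- log_likelihood(spec, log(D / Y), b)
  expect_gt(ll_hat, log_likelihood(spec, log(D / Y) + 0.01, b))
  expect_gt(ll_hat, log_likelihood(spec, log(D / Y) - 0.01, b))
})

test_that("with zero excess the likelihood tends to the expected-death terms", {
  lt <- const_lifetable(0.05)
  coh <- exp_cohort(40, hazards = 0.08, seed = 3)
  b <- duplicate_and_band(coh, 1, lt, width = 1 / 12)
  spec <- model_spec(1, 1, baseline = time_spec("constant", boundary = c(0, 7)))
  D <- sum(coh$status)
  # eta -> -inf: only d * log(lambda_P) survives (the -y*lambda_P constant
  # is dropped by construction)
  expect_equal(log_likelihood(spec, -40, b), D * log(0.05), tolerance = 1e-8)
})

test_that("banded log-likelihood matches brute-force quadrature exactly for
           piecewise-constant hazards", {
  lt <- const_lifetable(0.03)
  set.seed(9)
  n <- 12
  status <- rbinom(n, 1, 0.8)
  coh <- as_cohort(data.frame(
    id = 1:n, time = round(runif(n, 0.3, 6), 3),
    status = status,
    event_type = ifelse(status == 1, sample(1:2, n, TRUE), 0L),
    age = sample(55:75, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE), year = 1995L,
    x1 = rbinom(n, 1, 0.5)))

  spec <- model_spec(2, 2,
                     baseline = time_spec("constant", boundary = c(0, 7)),
                     covariates = list(x1 = covariate_effect(TRUE, 2)))
  theta <- c(-2.2, 0.4, 0.5, -0.3)
  b <- duplicate_and_band(coh, 2, lt, width = 1 / 12)
  ll_banded <- log_likelihood(spec, theta, b)

  hazards <- list(
    function(u, row) exp(theta[1] + theta[3] * row$x1),
    function(u, row) 0.03 + exp(theta[1] + theta[2] + (theta[3] + theta[4]) * row$x1))
  ll_exact <- oracle_loglik(coh, hazards, step = 1 / 400)
  # the banded version drops the -integral(lambda_P) constant
  const <- -0.03 * sum(coh$time)
  expect_equal(ll_banded, ll_exact - const, tolerance = 1e-6 * nrow(coh))
})

test_that("joint MLE agrees with a derivative-free optimiser on the exact
           likelihood for a small cohort", {
  lt <- const_lifetable(0.04)
  sc <- quick_scenario(n = 18, h1 = 0.15, b2 = 0.4,
                       lifetable = lt, alpha = c(x2 = 0.5))
  coh <- simulate_cohort(sc, seed = 21)
  # ensure both event types occur
  stopifnot(sum(coh$event_type == 1) > 1, sum(coh$event_type == 2) > 1)
  spec <- model_spec(2, 2,
                     baseline = time_spec("linear", boundary = c(0, 7)),
                     covariates = list(x2 = covariate_effect(TRUE)))
  # fine bands so the Poisson approximation error is far below the tolerance
  b <- duplicate_and_band(coh, 2, lt, width = 1 / 240)
  fit <- fit_crexhaz(spec, b)
  expect_true(fit$converged)

  make_hazards <- function(th) list(
    function(u, row) exp(th[1] + th[2] * u + th[4] * row$x2),
    function(u, row) oracle_pop(lt, row, u) +
      exp(th[1] + th[2] * u + th[3] + th[4] * row$x2))
  o <- oracle_fit(coh, make_hazards, init = c(-2, 0, 0, 0), step = 1 / 800)
  expect_lt(max(abs(coef(fit) - o$par)), 1e-4)
  # banded loglik at the MLE equals the exact one minus the dropped
  # -integral(lambda_P) constant (death stratum only)
  expect_equal(-o$value,
               log_likelihood(spec, coef(fit), b) - 0.04 * sum(coh$time),
               tolerance = 1e-3)
})

test_that("two-strata constant fit reproduces the closed forms", {
  coh <- exp_cohort(400, hazards = c(0.08, 0.15), seed = 4)
  b <- duplicate_and_band(coh, 2, width = 1 / 12)
  spec <- model_spec(2, 2, baseline = time_spec("constant", boundary = c(0, 7)),
                     bj = list("2" = time_spec("constant")))
  fit <- fit_crexhaz(spec, b)
  D <- table(factor(coh$event_type, levels = 0:2))
  Y <- sum(coh$time)
  h1 <- unname(D["1"]) / Y
  h2 <- unname(D["2"]) / Y
  expect_equal(unname(exp(coef(fit)["base1"])), h1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["b2"]), log(h2 / h1), tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  # covariance is symmetric with non-negative diagonal
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(diag(fit$vcov) >= 0))
})

test_that("overflowing linear predictors raise a diagnostic", {
  coh <- exp_cohort(30, hazards = 0.1, seed = 5)
  b <- duplicate_and_band(coh, 1, width = 1 / 6)
  spec <- model_spec(1, 1, baseline = time_spec("constant", boundary = c(0, 7)))
  expect_error(log_likelihood(spec, 800, b), "overflow")
})

test_that("flexible model nests the proportional-pattern model", {
  sc <- default_scenario(n = 250)
  coh <- simulate_cohort(sc, seed = 31)
  b <- duplicate_and_band(coh, 3, sc$lifetable, cut_times = 1)
  covs <- list(sexf = covariate_effect(TRUE, 3))
  base <- time_spec("cubic_spline", knots = 1)
  fit3 <- fit_crexhaz(model_spec(3, 3, base, list(
    "2" = time_spec("constant"), "3" = time_spec("constant")), covs), b)
  fit4 <- fit_crexhaz(model_spec(3, 3, base, list(
    "2" = time_spec("constant"),
    "3" = time_spec("cubic_spline", knots = 1)), covs), b)
  expect_gte(fit4$loglik, fit3$loglik)
  expect_equal(fit4$n_params - fit3$n_params, 4L)
})

test_that("halving the band width leaves the fit essentially unchanged", {
  # well-conditioned two-event model: compare coefficients directly
  sc <- scenario_spec(n = 400, J = 2, death_stratum = 2,
                      baseline = time_spec("cubic_spline", knots = 1,
                                           boundary = c(0, 7)),
                      gamma = c(-2.8, -2.1, -2.4, -3.0, -2.9),
                      bj = list("2" = time_spec("constant")),
                      bj_coefs = list("2" = 0.5),
                      alpha = c(x2 = 0.5), beta = list(),
                      lifetable = make_lifetable())
  coh <- simulate_cohort(sc, seed = 17)
  spec <- truth_spec(sc)
  f1 <- fit_crexhaz(spec, duplicate_and_band(coh, 2, sc$lifetable,
                                             width = 1 / 12, cut_times = 1))
  f2 <- fit_crexhaz(spec, duplicate_and_band(coh, 2, sc$lifetable,
                                             width = 1 / 24, cut_times = 1))
  expect_lt(max(abs(coef(f1) - coef(f2))), 5e-3)

  # full reference scenario: the weakly identified late spline directions
  # make raw coefficients ridge-sensitive, so compare the fitted log
  # hazards (the quantity the likelihood actually controls)
  sc3 <- default_scenario(n = 300)
  coh3 <- simulate_cohort(sc3, seed = 17)
  spec3 <- truth_spec(sc3)
  g1 <- fit_crexhaz(spec3, duplicate_and_band(coh3, 3, sc3$lifetable,
                                              width = 1 / 12, cut_times = 1))
  g2 <- fit_crexhaz(spec3, duplicate_and_band(coh3, 3, sc3$lifetable,
                                              width = 1 / 24, cut_times = 1))
  tt <- seq(0.1, 6, by = 0.25)
  for (j in 1:3) {
    e1 <- linear_predictor(g1$spec, coef(g1), j, tt, c(sexf = 1, agez = 0.5))
    e2 <- linear_predictor(g2$spec, coef(g2), j, tt, c(sexf = 1, agez = 0.5))
    expect_lt(max(abs(e1 - e2)), 0.02)
  }
})
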