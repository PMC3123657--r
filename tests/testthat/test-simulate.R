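test_that("zero hazards and no dropout censor everyone at the horizon", {
  sc <- scenario_spec(n = 50, J = 2, death_stratum = 2,
                      baseline = time_spec("constant", boundary = c(0, 7)),
                      gamma = -1e4,
                      bj = list("2" = time_spec("constant")),
                      bj_coefs = list("2" = 0),
                      alpha = c(x2 = 0), beta = list(),
                      lifetable = NULL, horizon = 7, dropout = 0)
  coh <- simulate_cohort(sc, seed = 1)
  expect_true(all(coh$status == 0))
  expect_true(all(coh$event_type == 0))
  expect_true(all(coh$time == 7))
})

test_that("single constant hazard reproduces the exponential mean", {
  sc <- scenario_spec(n = 40000, J = 1, death_stratum = 1,
                      baseline = time_spec("constant", boundary = c(0, 60)),
                      gamma = log(0.5), bj = NULL, bj_coefs = NULL,
                      alpha = c(x2 = 0), beta = list(),
                      lifetable = NULL, horizon = 60, dropout = 0,
                      grid_step = 1 / 48)
  coh <- simulate_cohort(sc, seed = 2)
  expect_gt(mean(coh$status), 0.999)     # horizon effectively infinite
  expect_equal(mean(coh$time), 1 / 0.5, tolerance = 0.02)
})

test_that("competing exponentials split events in proportion to hazards", {
  h1 <- 0.2; h2 <- 0.5
  sc <- scenario_spec(n = 30000, J = 2, death_stratum = 2,
                      baseline = time_spec("constant", boundary = c(0, 40)),
                      gamma = log(h1),
                      bj = list("2" = time_spec("constant")),
                      bj_coefs = list("2" = log(h2 / h1)),
                      alpha = c(x2 = 0), beta = list(),
                      lifetable = NULL, horizon = 40, dropout = 0,
                      grid_step = 1 / 48)
  coh <- simulate_cohort(sc, seed = 3)
  ev <- coh$event_type[coh$status == 1]
  expect_equal(mean(ev == 1), h1 / (h1 + h2), tolerance = 0.01)
})

test_that("the excess-death event responds to the population hazard", {
  # zero excess (very negative b2): deaths arise from the life table only
  lt <- const_lifetable(0.05)
  sc <- scenario_spec(n = 20000, J = 2, death_stratum = 2,
                      baseline = time_spec("constant", boundary = c(0, 7)),
                      gamma = log(0.0001),
                      bj = list("2" = time_spec("constant")),
                      bj_coefs = list("2" = 0),
                      alpha = c(x2 = 0), beta = list(),
                      lifetable = lt, horizon = 7, dropout = 0)
  coh <- simulate_cohort(sc, seed = 4)
  # P(death by 7) = 1 - exp(-0.05 * 7), +/- MC error
  expect_equal(mean(coh$event_type == 2), 1 - exp(-0.05 * 7),
               tolerance = 0.01)
})

test_that("dropout calibration hits its target on an independent draw", {
  sc <- default_scenario(n = 20000, dropout = 0.15)
  expect_identical(calibrate_dropout(sc, target = 0), 0)
  for (target in c(0.15, 0.30)) {
    sc$dropout <- target
    sc$dropout_rho <- calibrate_dropout(sc, target)
    coh <- simulate_cohort(sc, seed = 1234)
    realized <- mean(coh$status == 0 & coh$time < sc$horizon)
    expect_lt(abs(realized - target), 0.011)
  }
})

test_that("identical seeds reproduce identical cohorts", {
  sc <- default_scenario(n = 200, dropout = 0.15)
  sc$dropout_rho <- calibrate_dropout(sc)
  c1 <- simulate_cohort(sc, seed = 31)
  c2 <- simulate_cohort(sc, seed = 31)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- simulate_cohort(sc, seed = 32)
  expect_false(identical(c1$time, c3$time))
})

test_that("registry extracts carry the requested stage composition", {
  raw <- simulate_registry_cohort(n = 300, n_unknown_stage = 12, n_stage4 = 8,
                                  seed = 2)
  expect_equal(sum(raw$stage == "unknown"), 12)
  expect_equal(sum(raw$stage == "IV"), 8)
  expect_error(simulate_registry_cohort(10, 8, 5), "more flagged")
})
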