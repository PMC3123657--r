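# Fixtures built in code: life tables, tiny cohorts, small scenarios.

# life table with the same rate everywhere
const_lifetable <- function(rate = 0.01, ages = 0:109, years = 1988:2012) {
  g <- expand.grid(age = ages, year = years, sex = c("male", "female"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- rate
  lifetable(g)
}

# minimal clean cohort table
tiny_cohort_df <- function() {
  data.frame(id = 1:3,
             time = c(2.0, 1.3, 4.5),
             status = c(1, 1, 0),
             event_type = c(1, 3, 0),
             age = c(61.2, 70, 55.4),
             sex = c("male", "female", "male"),
             year = c(1995, 1995, 1996),
             x1 = c(0, 1, 1))
}

# cohort drawn from exponential competing risks with known constant
# hazards (no population mortality), used for closed-form anchors
exp_cohort <- function(n, hazards, horizon = 7, seed = 1) {
  set.seed(seed)
  J <- length(hazards)
  tm <- sapply(hazards, function(h) stats::rexp(n, h))
  tm <- matrix(tm, n, J)
  jm <- max.col(-tm, ties.method = "first")
  t1 <- tm[cbind(seq_len(n), jm)]
  obs <- t1 < horizon
  as_cohort(data.frame(id = seq_len(n),
                       time = pmin(t1, horizon),
                       status = as.numeric(obs),
                       event_type = ifelse(obs, jm, 0L),
                       age = sample(50:70, n, replace = TRUE),
                       sex = sample(c("male", "female"), n, replace = TRUE),
                       year = 1995,
                       x1 = stats::rbinom(n, 1, 0.5)))
}

# small two-event scenario (constant baselines) for fast simulation fits
quick_scenario <- function(n = 300, h1 = 0.10, b2 = 0.5, dropout = 0,
                           lifetable = NULL, alpha = c(x2 = 0.4),
                           horizon = 7) {
  scenario_spec(n = n, J = 2, death_stratum = 2,
                baseline = time_spec("constant", boundary = c(0, horizon)),
                gamma = log(h1),
                bj = list("2" = time_spec("constant")),
                bj_coefs = list("2" = b2),
                alpha = alpha, beta = list(),
                lifetable = lifetable, horizon = horizon, dropout = dropout)
}
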