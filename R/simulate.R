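#' Simulation scenario for the estimator-performance study
#'
#' Bundles the true data-generating process of a competing-risks cohort
#' with excess mortality: `J` event types whose cause-specific hazards
#' share the baseline `lambda_1(t) = exp(s(t)' gamma)` through
#' between-event log hazard ratios `b_j(t)`, covariate effects split into
#' shared (`alpha`) and event-specific (`beta`) parts, and — for the
#' death stratum — an additive population hazard looked up in a life
#' table at the subject's attained age, year, and sex.  Subjects carry
#' three independent prognostic factors: `sexf` (balanced binary, also
#' the life-table sex), `x2` (balanced binary), and `agez` (age at
#' diagnosis, integer years from a truncated normal, standardised; also
#' the life-table age).  Follow-up is administratively censored at the
#' `horizon`, with optional exponential drop-out censoring calibrated to
#' a target rate.
#'
#' @param n Cohort size.
#' @param J Number of event types.
#' @param death_stratum Which event type is death.
#' @param baseline [time_spec] for the log baseline hazard (must have
#'   explicit boundary knots).
#' @param gamma True baseline spline coefficients.
#' @param bj Named list of [time_spec]s for `b_j(t)`, names `"2"..."J"`.
#' @param bj_coefs Named list of true coefficient vectors matching `bj`.
#' @param alpha Named vector of true shared covariate effects.
#' @param beta Named list (by stratum, e.g. `"3"`) of named vectors of
#'   true event-specific covariate-effect departures.
#' @param lifetable A [lifetable] or `NULL` for no population mortality.
#' @param horizon Administrative censoring time, years.
#' @param dropout Target drop-out censoring rate in `[0, 1)`.
#' @param dropout_rho Pre-calibrated exponential drop-out rate; `NULL`
#'   means calibrate on first use (see [calibrate_dropout()]).
#' @param age_mean,age_sd,age_range Age-at-diagnosis distribution
#'   (truncated normal, rounded to integer years).
#' @param year Calendar year of diagnosis.
#' @param grid_step Step of the fine grid used to invert cumulative
#'   hazards when drawing latent event times.
#' @return An object of class `crexhaz_scenario`.
#' @export
scenario_spec <- function(n = 1000, J = 3, death_stratum = 3,
                          baseline = time_spec("cubic_spline", knots = 1,
                                               boundary = c(0, 7)),
                          gamma = c(-2.99, -2.13, -2.40, -3.14, -2.93),
                          bj = list(
                            "2" = time_spec("constant"),
                            "3" = time_spec("cubic_spline", knots = 1,
                                            boundary = c(0, 7))),
                          bj_coefs = list(
                            "2" = 0.45,
                            "3" = c(1.13, -0.36, -0.73, -0.46, -0.57)),
                          alpha = c(sexf = -0.4, x2 = 0.5, agez = 0.3),
                          beta = list("3" = c(sexf = 0.8, agez = 0.6)),
                          lifetable = make_lifetable(),
                          horizon = 7, dropout = 0, dropout_rho = NULL,
                          age_mean = 65, age_sd = 9, age_range = c(40, 86),
                          year = 1995L, grid_step = 1 / 96) {
  J <- as.integer(J)
  if (J >= 2L) {
    stopifnot(setequal(names(bj), as.character(2:J)),
              setequal(names(bj_coefs), as.character(2:J)))
    bj <- bj[as.character(2:J)]
    bj_coefs <- bj_coefs[as.character(2:J)]
    for (j in names(bj))
      if (length(bj_coefs[[j]]) != basis_dim(bj[[j]]))
        stop("bj_coefs[['", j, "']] must have length ", basis_dim(bj[[j]]))
  } else {
    bj <- list(); bj_coefs <- list()
  }
  if (length(gamma) != basis_dim(baseline))
    stop("gamma must have length ", basis_dim(baseline))
  if (is.null(baseline$boundary))
    stop("the scenario baseline needs explicit boundary knots")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  for (j in names(beta))
    if (!j %in% as.character(2:J))
      stop("beta is only defined for event types 2..J")
  structure(list(n = as.integer(n), J = J,
                 death_stratum = as.integer(death_stratum),
                 baseline = baseline, gamma = gamma, bj = bj,
                 bj_coefs = bj_coefs, alpha = alpha, beta = beta,
                 lifetable = lifetable, horizon = horizon,
                 dropout = dropout, dropout_rho = dropout_rho,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 year = as.integer(year), grid_step = grid_step),
            class = "crexhaz_scenario")
}

#' Reference simulation scenario
#'
#' The documented study conditions of the performance harness: three
#' competing events including excess death, a one-knot spline baseline
#' log-hazard peaking near one year after diagnosis, a constant
#' between-event log hazard ratio for event 2, a spline `b_3(t)` for the
#' death event falling from a high early excess towards a level below the
#' reference hazard, three independent prognostic factors with |log HR|
#' at most 1.5, a realistic adult life table, administrative censoring at
#' 7 years, and `N` of 400 or 1000.
#'
#' @param n Cohort size (default 1000).
#' @param dropout Target drop-out censoring rate (0, 0.15 or 0.30 in the
#'   performance study).
#' @param ... Overrides passed to [scenario_spec()].
#' @return A `crexhaz_scenario`.
#' @export
default_scenario <- function(n = 1000, dropout = 0, ...)
  scenario_spec(n = n, dropout = dropout, ...)

#' @export
print.crexhaz_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: N = %d, %d event types (death = %d), dropout %.0f%%\n",
              x$n, x$J, x$death_stratum, 100 * x$dropout))
  cat(sprintf("  horizon %g years, %s population mortality\n", x$horizon,
              if (is.null(x$lifetable)) "no" else "life-table"))
  invisible(x)
}

#' Model specification matching a scenario's truth
#' @param scenario A `crexhaz_scenario`.
#' @return A `crexhaz_spec` whose fit recovers the scenario parameters.
#' @export
truth_spec <- function(scenario) {
  stopifnot(inherits(scenario, "crexhaz_scenario"))
  covn <- unique(c(names(scenario$alpha),
                   unlist(lapply(scenario$beta, names), use.names = FALSE)))
  covs <- lapply(covn, function(k) {
    diffs <- as.integer(names(scenario$beta)[vapply(scenario$beta, function(b)
      k %in% names(b), TRUE)])
    covariate_effect(common = k %in% names(scenario$alpha), differential = diffs)
  })
  names(covs) <- covn
  model_spec(scenario$J, scenario$death_stratum, scenario$baseline,
             scenario$bj, covs)
}

#' True coefficient vector of a scenario
#'
#' Ordered and named to match `coef()` of a fit of [truth_spec()].
#' @param scenario A `crexhaz_scenario`.
#' @return Named numeric vector.
#' @export
truth_theta <- function(scenario) {
  spec <- truth_spec(scenario)
  th <- scenario$gamma
  for (j in names(scenario$bj)) th <- c(th, scenario$bj_coefs[[j]])
  for (k in names(spec$covariates)) {
    ce <- spec$covariates[[k]]
    if (ce$common) th <- c(th, unname(scenario$alpha[k]))
    for (j in ce$differential) th <- c(th, unname(scenario$beta[[as.character(j)]][k]))
  }
  stats::setNames(th, param_names(spec))
}

# Draw covariates and latent event times (RNG state must already be set).
# Returns covariates plus the matrix of latent first-event times per type.
sim_latent <- function(sc, n) {
  sexf <- stats::rbinom(n, 1L, 0.5)
  x2 <- stats::rbinom(n, 1L, 0.5)
  age <- round(stats::rnorm(n, sc$age_mean, sc$age_sd))
  age <- pmin(pmax(age, sc$age_range[1L]), sc$age_range[2L])
  agez <- (age - sc$age_mean) / sc$age_sd
  X <- cbind(sexf = sexf, x2 = x2, agez = agez)

  g <- seq(0, sc$horizon, by = sc$grid_step)
  ncell <- length(g) - 1L
  mids <- (g[-1L] + g[-length(g)]) / 2
  lam1 <- exp(drop(build_basis(sc$baseline, mids) %*% sc$gamma))
  covn <- colnames(X)
  ab <- function(j) {  # per-subject log covariate effect on event j
    co <- stats::setNames(numeric(length(covn)), covn)
    co[names(sc$alpha)] <- co[names(sc$alpha)] + sc$alpha
    bj <- sc$beta[[as.character(j)]]
    if (!is.null(bj)) co[names(bj)] <- co[names(bj)] + bj
    drop(X %*% co)
  }

  Tmat <- matrix(Inf, n, sc$J)
  for (j in seq_len(sc$J)) {
    lamj <- if (j == 1L) lam1 else
      lam1 * exp(drop(build_basis(sc$bj[[as.character(j)]], mids) %*%
                        sc$bj_coefs[[as.character(j)]]))
    Gj <- c(0, cumsum(lamj * sc$grid_step))
    E <- stats::rexp(n)
    if (j == sc$death_stratum && !is.null(sc$lifetable)) {
      # all-cause death: population hazard + excess; invert per subject
      k <- floor(mids)
      ks <- sort(unique(k))
      rateK <- vapply(ks, function(kk)
        expected_hazard(sc$lifetable, age, sc$year, ifelse(sexf == 1, "female", "male"), kk),
        numeric(n))                               # n x length(ks)
      M <- t(rateK[, match(k, ks), drop = FALSE]) # ncell x n population rates
      H <- rbind(0, apply(M * sc$grid_step, 2, cumsum)) +
        outer(Gj, exp(ab(j)))
      idx <- .colSums(H < matrix(E, nrow(H), n, byrow = TRUE), nrow(H), n)
      inside <- idx <= ncell
      ii <- which(inside)
      if (length(ii)) {
        hc <- exp(ab(j))[ii] * lamj[idx[ii]] + M[cbind(idx[ii], ii)]
        Tmat[ii, j] <- g[idx[ii]] + (E[ii] - H[cbind(idx[ii], ii)]) / hc
      }
    } else if (Gj[length(Gj)] > 0) {
      v <- E / exp(ab(j))
      tt <- stats::approx(Gj, g, xout = v, rule = 1, ties = "ordered")$y
      Tmat[, j] <- ifelse(is.na(tt), Inf, tt)
    }
  }
  list(X = X, age = age, sexf = sexf, x2 = x2, agez = agez, Tmat = Tmat)
}

#' Calibrate the exponential drop-out rate to a target censoring share
#'
#' Finds the rate `rho` of an independent exponential drop-out time such
#' that the expected share of subjects censored by drop-out (before both
#' their first event and the administrative horizon) equals the target.
#' The expectation is taken over a large pilot cohort of latent event
#' times drawn with a fixed internal seed, so the calibration is
#' deterministic for a given scenario.
#'
#' @param scenario A `crexhaz_scenario`.
#' @param target Target drop-out rate in `[0, 1)`; default the
#'   scenario's.
#' @param pilot_n Pilot cohort size.
#' @param seed Pilot seed.
#' @return The drop-out rate `rho` (0 when the target is 0).
#' @export
calibrate_dropout <- function(scenario, target = scenario$dropout,
                              pilot_n = 20000, seed = 986527L) {
  stopifnot(inherits(scenario, "crexhaz_scenario"))
  if (target < 0 || target >= 1) stop("target must be in [0, 1)")
  if (target == 0) return(0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lat <- sim_latent(scenario, pilot_n)
  m <- pmin(apply(lat$Tmat, 1L, min), scenario$horizon)
  f <- function(r) mean(1 - exp(-r * m)) - target
  stats::uniroot(f, c(1e-8, 500), tol = 1e-10)$root
}

#' Simulate a competing-risks cohort with excess mortality
#'
#' Draws one cohort under the scenario: covariates, one latent time per
#' event type obtained by numerically inverting its cumulative hazard on
#' a fine grid (the death event uses the all-cause hazard, population
#' plus excess), the observed first event as the minimum, then
#' independent exponential drop-out censoring (calibrated to the
#' scenario's target rate if not pre-calibrated) and administrative
#' censoring at the horizon.
#'
#' @param scenario A `crexhaz_scenario`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `crexhaz_cohort` with covariates `sexf`, `x2`, `agez`.
#' @export
simulate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "crexhaz_scenario"))
  rho <- scenario$dropout_rho
  if (is.null(rho)) rho <- calibrate_dropout(scenario)
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n
  lat <- sim_latent(scenario, n)
  jmin <- max.col(-lat$Tmat, ties.method = "first")
  tmin <- lat$Tmat[cbind(seq_len(n), jmin)]
  cens <- pmin(if (rho > 0) stats::rexp(n, rho) else Inf, scenario$horizon)
  obs <- tmin < cens
  as_cohort(data.frame(
    id = seq_len(n),
    time = pmax(ifelse(obs, tmin, cens), 1e-9),
    status = as.numeric(obs),
    event_type = ifelse(obs, jmin, 0L),
    age = lat$age,
    sex = ifelse(lat$sexf == 1, "female", "male"),
    year = scenario$year,
    sexf = lat$sexf, x2 = lat$x2, agez = lat$agez))
}

#' Simulate a registry-style raw extract with a stage column
#'
#' Generates a synthetic population-based registry extract emulating the
#' structure of a curative-surgery colon-cancer cohort: competing first
#' events (local recurrence, distant metastasis, death) under the
#' reference scenario, plus a cancer-stage column in which a fixed number
#' of records have unknown stage and a fixed number are metastatic at
#' diagnosis (stage IV) — the two standard exclusion targets for
#' [apply_exclusions()].  Entirely synthetic; no real registry data are
#' used.
#'
#' @param n Number of records (default 1016).
#' @param n_unknown_stage Records with unknown stage (default 45).
#' @param n_stage4 Records metastatic at diagnosis (default 35).
#' @param seed Integer seed.
#' @return A raw data frame (not yet a cohort) with a `stage` column with
#'   levels `I`, `II`, `III`, `IV`, `unknown`.
#' @export
simulate_registry_cohort <- function(n = 1016, n_unknown_stage = 45,
                                     n_stage4 = 35, seed = NULL) {
  if (n_unknown_stage + n_stage4 > n)
    stop("more flagged records than records")
  coh <- simulate_cohort(default_scenario(n = n), seed = seed)
  raw <- as.data.frame(coh)
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.31, 0.34, 0.35))
  flagged <- sample.int(n, n_unknown_stage + n_stage4)
  stage[flagged[seq_len(n_unknown_stage)]] <- "unknown"
  stage[flagged[-seq_len(n_unknown_stage)]] <- "IV"
  raw$stage <- stage
  raw
}
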