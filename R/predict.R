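#' Fitted event-specific (excess) hazard curve
#'
#' Evaluates `exp(eta_j(t, x))` on a grid of times with a pointwise
#' delta-method confidence interval.  For the death stratum this is the
#' *excess* mortality hazard; add the population hazard externally for the
#' all-cause hazard.  On the default log scale the interval is
#' `exp(eta +/- z se(eta))`, which is always positive; `ci_scale =
#' "natural"` uses `exp(eta) +/- z se(eta) exp(eta)` and can reach or
#' cross zero, which is the relevant scale when asking whether an excess
#' hazard is distinguishable from zero.
#'
#' @param fit A converged `crexhaz_fit`.
#' @param stratum Event type in `1..J`.
#' @param times Evaluation times (years), within the baseline boundary.
#' @param x Named covariate values (default: all zero, i.e. the baseline).
#' @param level Confidence level (default 0.95).
#' @param ci_scale `"log"` (default) or `"natural"`.
#' @return Data frame with columns `time`, `hazard`, `lower`, `upper`,
#'   `se_log` (the delta-method standard error of the log hazard).
#' @export
predict_hazard <- function(fit, stratum, times, x = NULL, level = 0.95,
                           ci_scale = c("log", "natural")) {
  stopifnot(inherits(fit, "crexhaz_fit"))
  if (!fit$converged) warning("fit did not converge; curves are unreliable")
  ci_scale <- match.arg(ci_scale)
  Z <- design_rows(fit$spec, stratum, times, x)
  eta <- drop(Z %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Z %*% fit$vcov) * Z), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  h <- exp(eta)
  if (ci_scale == "log") {
    lo <- exp(eta - z * se); hi <- exp(eta + z * se)
  } else {
    lo <- h - z * se * h; hi <- h + z * se * h
  }
  data.frame(time = times, hazard = h, lower = lo, upper = hi, se_log = se)
}

#' Overall (all-events) survival curve
#'
#' The probability of surviving to `t` without any of the `J` event
#' types, `S(t|x) = exp(-sum_j Lambda_j(t|x))`, with each cumulative
#' hazard integrated band-wise on a fine grid of the fitted hazards.  By
#' default only the modelled (excess, for the death stratum) hazards
#' enter, giving the net-of-expected survival; with `lifetable` and the
#' subject's demographics the population hazard is added on the death
#' stratum, giving the observable all-cause survival, which is smaller at
#' every `t`.
#'
#' @param fit A converged `crexhaz_fit`.
#' @param times Evaluation times (years), within the baseline boundary.
#' @param x Named covariate values (default all zero).
#' @param lifetable,age,year,sex Population-hazard context; all four are
#'   required to include the expected mortality, and silently omitted
#'   when `lifetable` is `NULL`.
#' @param step Integration step in years (default 1/100).
#' @return Data frame with columns `time` and `surv`.
#' @export
overall_survival <- function(fit, times, x = NULL, lifetable = NULL,
                             age = NULL, year = NULL, sex = NULL,
                             step = 1 / 100) {
  stopifnot(inherits(fit, "crexhaz_fit"))
  if (any(times < 0)) stop("times must be non-negative")
  tmax <- max(times)
  if (tmax == 0) return(data.frame(time = times, surv = rep(1, length(times))))
  grid <- seq(0, tmax, by = step)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  mids <- (grid[-1L] + grid[-length(grid)]) / 2
  dt <- diff(grid)
  tot <- numeric(length(mids))
  for (j in seq_len(fit$spec$J))
    tot <- tot + exp(linear_predictor(fit$spec, fit$coefficients, j, mids, x))
  if (!is.null(lifetable)) {
    if (is.null(age) || is.null(year) || is.null(sex))
      stop("age, year and sex are required with a lifetable")
    tot <- tot + expected_hazard(lifetable, age, year, sex, mids)
  }
  cum <- c(0, cumsum(tot * dt))
  Lam <- stats::approx(grid, cum, xout = times, rule = 2)$y
  data.frame(time = times, surv = exp(-Lam))
}
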