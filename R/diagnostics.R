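#' Schoenfeld-residual pattern of between-event hazard ratios
#'
#' Step 1 of the model-building strategy: fit a proportional-hazards
#' partial-likelihood model (Breslow tie handling) on the duplicated
#' data, with one dummy covariate per non-reference event type (so the
#' dummy coefficients are constant between-event log hazard ratios), and
#' inspect the scaled Schoenfeld residuals of those dummies over event
#' time.  A flat smooth suggests a constant `b_j`; a trending smooth
#' suggests a time-dependent `b_j(t)`.  The output is advisory and
#' graphical in spirit; the formal check remains the 4-df
#' likelihood-ratio test of [lr_test()].
#'
#' @param cohort A `crexhaz_cohort`.
#' @param J Number of event types.
#' @param covariates Covariate columns to adjust for (default: the
#'   cohort's covariates).
#' @param smooth_frac Running-mean window as a share of the number of
#'   events (default 0.2).
#' @return A list of class `crexhaz_schoenfeld`, one element per
#'   non-reference event type: a list with `series` (data frame `time`,
#'   `residual`, `smooth`) and `slope` (data frame `slope`, `se`,
#'   `lower`, `upper` from a least-squares trend of the residuals on
#'   event time).  Empty when `J = 1`.
#' @export
schoenfeld_pattern <- function(cohort, J, covariates = attr(cohort, "covariates"),
                               smooth_frac = 0.2) {
  stopifnot(inherits(cohort, "crexhaz_cohort"))
  J <- as.integer(J)
  out <- structure(list(), class = "crexhaz_schoenfeld")
  if (J < 2L) return(out)
  n <- nrow(cohort)
  dup <- do.call(rbind, lapply(seq_len(J), function(j) {
    d <- as.data.frame(cohort)
    d$.event <- as.numeric(cohort$event_type == j)
    for (jj in 2:J) d[[paste0(".ev", jj)]] <- as.numeric(j == jj)
    d
  }))
  dummies <- paste0(".ev", 2:J)
  rhs <- paste(c(dummies, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, .event) ~", rhs))
  cf <- survival::coxph(fml, data = dup, ties = "breslow")
  if (is.null(cf$coefficients) || anyNA(cf$coefficients))
    stop("proportional-hazards fit on duplicated data failed")
  sr <- stats::residuals(cf, type = "scaledsch")
  et <- as.numeric(rownames(sr))
  colnames(sr) <- names(cf$coefficients)
  for (jj in 2:J) {
    res <- sr[, paste0(".ev", jj)]
    k <- max(3L, ceiling(smooth_frac * length(res)))
    sm <- stats::filter(res, rep(1 / k, k), sides = 2)
    tr <- stats::lm(res ~ et)
    sl <- summary(tr)$coefficients["et", , drop = TRUE]
    out[[paste0("event", jj)]] <- list(
      series = data.frame(time = et, residual = res, smooth = as.numeric(sm)),
      slope = data.frame(slope = sl[["Estimate"]], se = sl[["Std. Error"]],
                         lower = sl[["Estimate"]] - 1.96 * sl[["Std. Error"]],
                         upper = sl[["Estimate"]] + 1.96 * sl[["Std. Error"]]))
  }
  out
}

#' Candidate time functions for baseline selection
#'
#' The six standard candidates: constant, linear, quadratic, cubic,
#' cubic regression spline with one knot at 1 year, and cubic regression
#' spline with two knots at 1 and 5 years (1 to 6 df).
#'
#' @return Named list of [time_spec]s.
#' @export
baseline_candidates <- function() list(
  constant = time_spec("constant"),
  linear = time_spec("linear"),
  quadratic = time_spec("quadratic"),
  cubic = time_spec("cubic"),
  spline_1knot = time_spec("cubic_spline", knots = 1),
  spline_2knots = time_spec("cubic_spline", knots = c(1, 5)))

#' Select the baseline time function for one event type by AIC
#'
#' Step 2 of the model-building strategy: treating every other event as
#' censoring, fit one single-event model per candidate time function for
#' the log baseline hazard and rank them by AIC (ties broken by fewer
#' parameters).
#'
#' @param cohort A `crexhaz_cohort`.
#' @param stratum The event type whose baseline is selected.
#' @param lifetable Optional [lifetable]; supply it when `stratum` is the
#'   death event so the candidates model the *excess* hazard.
#' @param candidates Named list of [time_spec]s (default
#'   [baseline_candidates()]).
#' @param covariates Covariates given a common effect in each candidate
#'   fit (default none: baseline-only fits).
#' @param width Band width (default monthly).
#' @return A list of class `crexhaz_baseline_selection` with `winner`
#'   (candidate name), `spec`, `table` (the AIC ranking with a `df`
#'   column), and `fits`.
#' @export
select_baseline <- function(cohort, stratum, lifetable = NULL,
                            candidates = baseline_candidates(),
                            covariates = character(), width = 1 / 12) {
  stopifnot(inherits(cohort, "crexhaz_cohort"))
  if (!any(cohort$event_type == stratum))
    stop("no events of type ", stratum, " in the cohort")
  one <- as.data.frame(cohort)
  one$status <- as.numeric(one$event_type == stratum)
  one$event_type <- one$status
  one <- as_cohort(one, attr(cohort, "covariates"))
  covs <- stats::setNames(
    replicate(length(covariates), covariate_effect(common = TRUE),
              simplify = FALSE), covariates)
  knots <- sort(unique(unlist(lapply(candidates, `[[`, "knots"))))
  bands <- duplicate_and_band(one, 1L, lifetable, width = width,
                              cut_times = knots)
  fits <- lapply(candidates, function(cs)
    fit_crexhaz(model_spec(1L, 1L, baseline = cs, covariates = covs), bands))
  tab <- aic_compare(fits)
  structure(list(winner = tab$model[1L],
                 spec = candidates[[tab$model[1L]]],
                 table = tab, fits = fits),
            class = "crexhaz_baseline_selection")
}

#' @export
print.crexhaz_baseline_selection <- function(x, ...) {
  cat("Baseline time-function selection (AIC):\n")
  print(x$table, row.names = FALSE)
  cat("winner:", x$winner, "\n")
  invisible(x)
}
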