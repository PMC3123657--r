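#' Three-step model-building strategy for joint excess-hazard fits
#'
#' Runs the full analysis strategy on a cohort:
#'
#' 1. *Pattern of the between-event hazard ratios*: Schoenfeld residuals
#'    of the event-type dummies from a proportional-hazards fit on
#'    duplicated data ([schoenfeld_pattern()]), advisory; the formal
#'    decision is the likelihood-ratio test of a constant `b_j` against a
#'    one-knot spline `b_j(t)` (4 df per event), performed here for each
#'    non-reference event.
#' 2. *Baseline time function* for the reference event, selected by AIC
#'    among the six candidates ([select_baseline()]).
#' 3. *Joint fit* with the selected baseline and `b_j` forms, with
#'    event-specific (differential) covariate effects imposed on the
#'    death event and, for each covariate (or covariate group), a
#'    likelihood-ratio test of a common effect on the non-death events
#'    against event-specific effects.
#'
#' @param cohort A `crexhaz_cohort`.
#' @param lifetable A [lifetable] for the expected mortality of the death
#'   stratum (required).
#' @param J Number of event types.
#' @param death_stratum Which event type is death (default `J`).
#' @param covariates Covariate columns (default: the cohort's).
#' @param groups Optional named list grouping covariate columns that are
#'   tested jointly (e.g. the indicator columns of a factor); ungrouped
#'   covariates are tested alone (1 df).
#' @param width Band width (default monthly).
#' @param alpha_level Significance level used when choosing between
#'   constant and time-dependent `b_j` (default 0.05).
#' @return A list of class `crexhaz_strategy` with elements `step1`
#'   (Schoenfeld pattern and per-event 4-df LR tests of time dependence,
#'   plus the chosen `b_j` families), `step2` (the baseline selection),
#'   and `step3` (`fit`, the common-vs-differential LR `tests` per
#'   covariate group, and per-event hazard ratios).
#' @export
run_strategy <- function(cohort, lifetable, J, death_stratum = J,
                         covariates = attr(cohort, "covariates"),
                         groups = NULL, width = 1 / 12,
                         alpha_level = 0.05) {
  stopifnot(inherits(cohort, "crexhaz_cohort"), inherits(lifetable, "lifetable"))
  J <- as.integer(J)
  if (J < 2L) stop("the strategy needs at least 2 event types")
  if (is.null(groups)) groups <- as.list(stats::setNames(covariates, covariates))
  ungrouped <- setdiff(covariates, unlist(groups))
  groups <- c(groups, as.list(stats::setNames(ungrouped, ungrouped)))

  ## step 1: residual pattern + formal 4-df LR tests of time dependence
  pattern <- schoenfeld_pattern(cohort, J, covariates)
  covs <- stats::setNames(
    lapply(covariates, function(k)
      covariate_effect(common = TRUE, differential = death_stratum)),
    covariates)
  spline1 <- time_spec("cubic_spline", knots = 1)
  bands <- duplicate_and_band(cohort, J, lifetable, width = width,
                              cut_times = c(1, 5))
  bj_flex <- stats::setNames(replicate(J - 1L, spline1, simplify = FALSE),
                             as.character(2:J))
  fit_flex <- fit_crexhaz(model_spec(J, death_stratum, spline1, bj_flex, covs),
                          bands)
  td_tests <- list()
  bj_chosen <- bj_flex
  for (j in as.character(2:J)) {
    bj_red <- bj_flex
    bj_red[[j]] <- time_spec("constant")
    fit_red <- fit_crexhaz(model_spec(J, death_stratum, spline1, bj_red, covs),
                           bands)
    tt <- lr_test(fit_red, fit_flex)
    td_tests[[paste0("b", j, "_time_dependence")]] <- tt
    if (tt$p_value >= alpha_level) bj_chosen[[j]] <- time_spec("constant")
  }

  ## step 2: baseline for the reference event (plain cause-specific fit)
  sel <- select_baseline(cohort, 1L,
                         lifetable = if (death_stratum == 1L) lifetable,
                         width = width)

  ## step 3: joint fit + common-vs-differential LR tests per covariate group
  spec3 <- model_spec(J, death_stratum, sel$spec, bj_chosen, covs)
  fit3 <- fit_crexhaz(spec3, bands)
  nondeath <- setdiff(2:J, death_stratum)
  eff_tests <- list()
  for (gname in names(groups)) {
    if (!length(nondeath)) break
    covs_alt <- covs
    for (k in groups[[gname]])
      covs_alt[[k]] <- covariate_effect(
        common = TRUE, differential = sort(c(covs[[k]]$differential, nondeath)))
    fit_alt <- fit_crexhaz(model_spec(J, death_stratum, sel$spec, bj_chosen,
                                      covs_alt), bands)
    eff_tests[[gname]] <- lr_test(fit3, fit_alt)
  }
  hrs <- do.call(rbind, lapply(covariates, function(k)
    do.call(rbind, lapply(seq_len(J), function(j) hazard_ratio(fit3, k, j)))))

  structure(list(
    step1 = list(pattern = pattern, tests = td_tests,
                 bj_families = vapply(bj_chosen, `[[`, "", "family")),
    step2 = sel,
    step3 = list(fit = fit3, tests = eff_tests, hazard_ratios = hrs)),
    class = "crexhaz_strategy")
}

#' @export
print.crexhaz_strategy <- function(x, ...) {
  cat("Three-step joint excess-hazard analysis\n")
  cat("step 1 - time dependence of between-event hazard ratios:\n")
  for (nm in names(x$step1$tests)) {
    tt <- x$step1$tests[[nm]]
    cat(sprintf("  %s: LR = %.2f on %d df, p = %.3g\n",
                nm, tt$statistic, tt$df, tt$p_value))
  }
  cat("  chosen forms:", paste(names(x$step1$bj_families),
                               x$step1$bj_families, sep = "=",
                               collapse = ", "), "\n")
  cat("step 2 - baseline selection: winner", x$step2$winner, "\n")
  cat("step 3 - joint fit:\n")
  print(x$step3$fit)
  for (nm in names(x$step3$tests)) {
    tt <- x$step3$tests[[nm]]
    cat(sprintf("  common-vs-differential %s: LR = %.2f on %d df, p = %.3g\n",
                nm, tt$statistic, tt$df, tt$p_value))
  }
  invisible(x)
}

#' Serialise a strategy report to a directory
#'
#' Writes the step-1 residual series and tests, the step-2 AIC table,
#' the step-3 coefficient table, hazard ratios and tests as CSVs plus a
#' JSON manifest naming every artefact.
#'
#' @param x A `crexhaz_strategy`.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list echoed in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_strategy <- function(x, dir, config = NULL) {
  stopifnot(inherits(x, "crexhaz_strategy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  res <- do.call(rbind, lapply(names(x$step1$pattern), function(nm)
    cbind(event = nm, x$step1$pattern[[nm]]$series)))
  if (!is.null(res)) utils::write.csv(res, f("step1_residuals.csv"),
                                      row.names = FALSE)
  write_tests_csv(x$step1$tests, f("step1_tests.csv"))
  utils::write.csv(x$step2$table, f("step2_aic.csv"), row.names = FALSE)
  write_fit_csv(x$step3$fit, f("step3_coefficients.csv"))
  utils::write.csv(x$step3$hazard_ratios, f("step3_hazard_ratios.csv"),
                   row.names = FALSE)
  write_tests_csv(x$step3$tests, f("step3_tests.csv"))
  manifest <- list(
    artefacts = list(step1_residuals = "step1_residuals.csv",
                     step1_tests = "step1_tests.csv",
                     step2_aic = "step2_aic.csv",
                     step3_coefficients = "step3_coefficients.csv",
                     step3_hazard_ratios = "step3_hazard_ratios.csv",
                     step3_tests = "step3_tests.csv"),
    bj_families = as.list(x$step1$bj_families),
    baseline_winner = x$step2$winner,
    config = config)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
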