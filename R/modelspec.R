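#' Covariate effect structure
#'
#' Describes how one covariate acts across event types: a *common* (shared)
#' log hazard ratio `alpha` applying to every event type, and optional
#' *differential* event-specific departures `beta_j` for a subset of the
#' non-reference event types.  The hazard ratio of the covariate on event
#' `j` is `exp(alpha + beta_j)` with `beta_j = 0` wherever no differential
#' effect is declared; the reference event (type 1) never has a
#' differential effect, which identifies the decomposition.
#'
#' @param common Logical: include the shared effect `alpha` (default TRUE).
#' @param differential Integer vector of event types in `2..J` that get
#'   their own departure `beta_j`.
#' @return A list of class `covariate_effect`.
#' @export
covariate_effect <- function(common = TRUE, differential = integer()) {
  structure(list(common = isTRUE(common),
                 differential = sort(unique(as.integer(differential)))),
            class = "covariate_effect")
}

#' Joint competing-risks excess-hazard model specification
#'
#' Defines the joint model for `J` event-specific hazards sharing a
#' baseline through between-event log hazard ratios.  On the log scale,
#' for event type `j`, time `u` and covariates `x`:
#' \deqn{\eta_j(u, x) = s(u)'\gamma + b_j(u) + \sum_k (\alpha_k + \beta_{jk}) x_k,}
#' with `b_1 = 0` and `beta_1k = 0` for identifiability.  The hazard of a
#' non-death event type is `exp(eta_j)`; for the designated death stratum
#' the *all-cause* hazard is `lambda_P + exp(eta_j)` where `lambda_P` is
#' the known population hazard, so `exp(eta_j)` is the excess mortality
#' hazard.  A constant `b_j` for every event gives the
#' proportional-pattern model; spline `b_j(t)` terms give the flexible
#' time-dependent-ratio model, and the two differ by 4 df per event when
#' the spline has one interior knot.
#'
#' @param J Number of event types.
#' @param death_stratum Which event type is death (gets the expected-
#'   hazard decomposition when bands carry a life table).  Default `J`.
#' @param baseline A [time_spec] for the log baseline hazard of the
#'   reference event type 1.
#' @param bj A named list of [time_spec]s for the between-event log
#'   hazard ratios `b_j(t)`, names `"2"`, ..., `"J"`; a `"constant"`
#'   spec gives that event a proportional (time-constant) ratio.
#'   Default: constant for every event.
#' @param covariates Named list of [covariate_effect()]s; names must be
#'   covariate columns of the band table used for fitting.
#' @return An object of class `crexhaz_spec`.
#' @export
model_spec <- function(J, death_stratum = J,
                       baseline = time_spec("cubic_spline", knots = 1),
                       bj = NULL, covariates = list()) {
  J <- as.integer(J)
  if (J < 1L) stop("J must be at least 1")
  death_stratum <- as.integer(death_stratum)
  if (!death_stratum %in% seq_len(J))
    stop("death_stratum must be one of 1..J")
  stopifnot(inherits(baseline, "time_spec"))
  if (J >= 2L) {
    if (is.null(bj))
      bj <- stats::setNames(replicate(J - 1L, time_spec("constant"),
                                      simplify = FALSE), as.character(2:J))
    if (!setequal(names(bj), as.character(2:J)))
      stop("bj must be a named list with one time_spec per event 2..J")
    bj <- bj[as.character(2:J)]
    for (s in bj) stopifnot(inherits(s, "time_spec"))
  } else bj <- list()
  if (length(covariates)) {
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      stop("covariates must be a named list")
    for (ce in covariates) {
      stopifnot(inherits(ce, "covariate_effect"))
      if (length(ce$differential) &&
          (any(ce$differential < 2L) || any(ce$differential > J)))
        stop("differential effects are only defined for event types 2..J")
    }
  }
  structure(list(J = J, death_stratum = death_stratum, baseline = baseline,
                 bj = bj, covariates = covariates),
            class = "crexhaz_spec")
}

#' @export
print.crexhaz_spec <- function(x, ...) {
  cat(sprintf("Joint model: %d event types, death stratum %d, %d parameters\n",
              x$J, x$death_stratum, n_params(x)))
  cat("  baseline log-hazard:", x$baseline$family,
      if (length(x$baseline$knots))
        paste0("(knots ", paste(x$baseline$knots, collapse = ", "), ")"), "\n")
  for (j in names(x$bj))
    cat(sprintf("  b_%s(t): %s (%d df)\n", j, x$bj[[j]]$family,
                basis_dim(x$bj[[j]])))
  for (k in names(x$covariates)) {
    ce <- x$covariates[[k]]
    cat(sprintf("  %s: %s%s\n", k,
                if (ce$common) "common effect" else "no common effect",
                if (length(ce$differential))
                  paste0(", differential on ", paste(ce$differential, collapse = ","))
                else ""))
  }
  invisible(x)
}

#' Total number of free parameters of a model specification
#' @param spec A `crexhaz_spec`.
#' @return Integer.
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "crexhaz_spec"))
  basis_dim(spec$baseline) +
    sum(vapply(spec$bj, basis_dim, 1L)) +
    sum(vapply(spec$covariates, function(ce)
      ce$common + length(ce$differential), 1L))
}

param_names <- function(spec) {
  nm <- paste0("base", seq_len(basis_dim(spec$baseline)))
  for (j in names(spec$bj)) {
    p <- basis_dim(spec$bj[[j]])
    nm <- c(nm, if (p == 1L) paste0("b", j) else paste0("b", j, ":", seq_len(p)))
  }
  for (k in names(spec$covariates)) {
    ce <- spec$covariates[[k]]
    if (ce$common) nm <- c(nm, paste0("alpha:", k))
    for (j in ce$differential) nm <- c(nm, paste0("beta", j, ":", k))
  }
  nm
}

# Resolve all data-dependent boundary knots against the observed bands.
resolve_spec <- function(spec, times) {
  spec$baseline <- resolve_boundary(spec$baseline, times)
  for (j in names(spec$bj)) spec$bj[[j]] <- resolve_boundary(spec$bj[[j]], times)
  spec
}

# Design matrix for the banded likelihood: one row per band row.
# Requires a resolved spec (explicit boundary knots).
build_design <- function(spec, stratum, tmid, xmat) {
  cols <- list(build_basis(spec$baseline, tmid))
  for (j in names(spec$bj)) {
    Bj <- build_basis(spec$bj[[j]], tmid)
    cols[[length(cols) + 1L]] <- Bj * (stratum == as.integer(j))
  }
  for (k in names(spec$covariates)) {
    ce <- spec$covariates[[k]]
    xk <- xmat[, k]
    if (ce$common) cols[[length(cols) + 1L]] <- xk
    for (j in ce$differential)
      cols[[length(cols) + 1L]] <- xk * (stratum == j)
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- param_names(spec)
  Z
}

#' Linear predictor of the joint model
#'
#' Evaluates the log event-specific (excess, for the death stratum)
#' hazard `eta_j(u, x)` for one event type at given times and covariate
#' values.  The reference event type 1 has `b_1 = 0` and `beta_1k = 0` by
#' construction.
#'
#' @param spec A `crexhaz_spec` with resolved boundary knots (specs from a
#'   fitted model always are).
#' @param theta Coefficient vector ordered as [param_names] (as returned
#'   by `coef()` on a fit).
#' @param stratum Event type in `1..J`.
#' @param times Evaluation times (years).
#' @param x Named numeric vector of covariate values; missing covariates
#'   default to 0.
#' @return Numeric vector `eta_j(times, x)`.
#' @export
linear_predictor <- function(spec, theta, stratum, times, x = NULL) {
  stopifnot(inherits(spec, "crexhaz_spec"))
  if (length(theta) != n_params(spec))
    stop("theta has wrong length (expected ", n_params(spec), ")")
  Z <- design_rows(spec, stratum, times, x)
  drop(Z %*% theta)
}

# Design rows for prediction at fixed covariate values.
design_rows <- function(spec, stratum, times, x = NULL) {
  stratum <- as.integer(stratum)
  if (!stratum %in% seq_len(spec$J)) stop("stratum must be in 1..J")
  covn <- names(spec$covariates)
  xv <- stats::setNames(numeric(length(covn)), covn)
  if (!is.null(x)) {
    if (is.null(names(x)) && length(x) == length(covn)) names(x) <- covn
    unknown <- setdiff(names(x), covn)
    if (length(unknown))
      stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
    xv[names(x)] <- x
  }
  xmat <- matrix(rep(xv, each = length(times)), nrow = length(times),
                 dimnames = list(NULL, covn))
  build_design(spec, rep(stratum, length(times)), times, xmat)
}
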