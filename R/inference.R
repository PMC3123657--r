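#' Hazard ratio of a covariate on an event type
#'
#' The log hazard ratio of covariate `k` on event type `j` is
#' `alpha_k + beta_jk` (the shared effect plus the event-specific
#' departure, either of which may be constrained to zero by the model
#' structure); the reference event type always has `beta_1k = 0`.  The
#' confidence interval is normal-theory on the log scale using the joint
#' covariance of the two coefficients.
#'
#' @param fit A converged `crexhaz_fit`.
#' @param covariate Covariate name.
#' @param stratum Event type in `1..J`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `covariate`, `stratum`, `log_hr`, `se`, `hr`,
#'   `lower`, `upper`.
#' @export
hazard_ratio <- function(fit, covariate, stratum, level = 0.95) {
  stopifnot(inherits(fit, "crexhaz_fit"))
  stratum <- as.integer(stratum)
  ce <- fit$spec$covariates[[covariate]]
  if (is.null(ce))
    stop("covariate '", covariate, "' is not in the model")
  terms <- c(if (ce$common) paste0("alpha:", covariate),
             if (stratum %in% ce$differential) paste0("beta", stratum, ":", covariate))
  if (!length(terms))
    stop("covariate '", covariate, "' has no effect on event type ", stratum,
         " in this model")
  est <- sum(fit$coefficients[terms])
  v <- sum(fit$vcov[terms, terms])
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(covariate = covariate, stratum = stratum, log_hr = est, se = se,
             hr = exp(est), lower = exp(est - z * se), upper = exp(est + z * se))
}

#' Likelihood-ratio test of nested fits
#'
#' `2 (loglik_alt - loglik_null)` compared to a chi-square with degrees
#' of freedom equal to the difference in parameter counts.  The two fits
#' must come from the same band table; comparing a constant between-event
#' log hazard ratio to a one-interior-knot cubic spline gives the 4-df
#' test of a proportional between-event pattern.
#'
#' @param null_fit,alt_fit Nested `crexhaz_fit` objects (null within alt).
#' @return A data frame of class `crexhaz_test` with `statistic`, `df`,
#'   `p_value`, `kind = "lr"`.
#' @export
lr_test <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "crexhaz_fit"), inherits(alt_fit, "crexhaz_fit"))
  df <- alt_fit$n_params - null_fit$n_params
  if (df < 1L) stop("alternative model must have more parameters than the null")
  if (!isTRUE(all.equal(null_fit$n_subjects, alt_fit$n_subjects)) ||
      abs(null_fit$person_time - alt_fit$person_time) > 1e-6)
    stop("fits must come from the same band table")
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < -1e-6)
    warning("negative LR statistic: models may not be nested or not converged")
  stat <- max(stat, 0)
  structure(data.frame(statistic = stat, df = df,
                       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                       kind = "lr"),
            class = c("crexhaz_test", "data.frame"))
}

#' Wald test of a linear hypothesis
#'
#' Tests `C theta = 0` with the quadratic-form statistic
#' `(C theta)' (C V C')^{-1} (C theta)` on `rank(C)` degrees of freedom.
#' A single-row contrast on one free parameter reduces to
#' `(estimate / se)^2` with 1 df.
#'
#' @param fit A converged `crexhaz_fit`.
#' @param contrast A contrast matrix (rows = restrictions, columns = the
#'   model coefficients), a single coefficient name, or a character
#'   vector of names (each tested as `= 0` jointly).
#' @return A `crexhaz_test` data frame with `statistic`, `df`, `p_value`,
#'   `kind = "wald"`.
#' @export
wald_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "crexhaz_fit"))
  p <- fit$n_params
  nm <- names(fit$coefficients)
  if (is.character(contrast)) {
    bad <- setdiff(contrast, nm)
    if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
    C <- matrix(0, length(contrast), p, dimnames = list(NULL, nm))
    C[cbind(seq_along(contrast), match(contrast, nm))] <- 1
  } else {
    C <- rbind(contrast)
    if (ncol(C) != p) stop("contrast must have ", p, " columns")
  }
  if (all(C == 0)) stop("contrast matrix is zero")
  r <- qr(C)$rank
  if (r < nrow(C)) C <- C[qr(t(C))$pivot[seq_len(r)], , drop = FALSE]
  ct <- drop(C %*% fit$coefficients)
  V <- C %*% fit$vcov %*% t(C)
  stat <- drop(crossprod(ct, solve(V, ct)))
  structure(data.frame(statistic = stat, df = r,
                       p_value = stats::pchisq(stat, r, lower.tail = FALSE),
                       kind = "wald"),
            class = c("crexhaz_test", "data.frame"))
}

#' Time-dependent hazard-ratio curve between event-specific hazards
#'
#' The fitted ratio of event type `j`'s baseline hazard to the reference
#' event's baseline hazard, `exp(b_j(t))`, with a pointwise delta-method
#' confidence interval on the log scale.  A constant-family `b_j` gives a
#' flat curve; the reference event returns a flat curve at 1 with zero
#' width.  Identically, the curve equals
#' `predict_hazard(j) / predict_hazard(1)` at `x = 0`.
#'
#' @param fit A converged `crexhaz_fit`.
#' @param stratum Event type in `1..J`.
#' @param times Evaluation times (years).
#' @param level Confidence level.
#' @return Data frame with `time`, `hr`, `lower`, `upper`, `se_log`.
#' @export
time_dependent_hr <- function(fit, stratum, times, level = 0.95) {
  stopifnot(inherits(fit, "crexhaz_fit"))
  stratum <- as.integer(stratum)
  spec <- fit$spec
  if (stratum == 1L)
    return(data.frame(time = times, hr = 1, lower = 1, upper = 1, se_log = 0))
  if (!as.character(stratum) %in% names(spec$bj))
    stop("stratum must be in 1..J")
  # design rows for b_j(t) alone: difference of the stratum-j and
  # reference-stratum rows at x = 0
  Z <- design_rows(spec, stratum, times) - design_rows(spec, 1L, times)
  eta <- drop(Z %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Z %*% fit$vcov) * Z), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = times, hr = exp(eta), lower = exp(eta - z * se),
             upper = exp(eta + z * se), se_log = se)
}

#' Rank fits by AIC
#'
#' Orders fits (on identical data) by the Akaike information criterion,
#' breaking ties in favour of fewer parameters.
#'
#' @param fits A (preferably named) list of `crexhaz_fit` objects.
#' @return Data frame with `model`, `loglik`, `df`, `aic`, `delta_aic`,
#'   ordered best first.
#' @export
aic_compare <- function(fits) {
  if (inherits(fits, "crexhaz_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "crexhaz_fit")))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  tab <- data.frame(model = nm,
                    loglik = vapply(fits, function(f) f$loglik, 1),
                    df = vapply(fits, function(f) f$n_params, 1L),
                    aic = vapply(fits, function(f) f$aic, 1))
  tab <- tab[order(tab$aic, tab$df), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  rownames(tab) <- NULL
  tab
}

#' Write a set of test results to a tidy CSV
#' @param tests Named list of `crexhaz_test` rows.
#' @param path Output path.
#' @return The written data frame, invisibly.
#' @export
write_tests_csv <- function(tests, path) {
  df <- do.call(rbind, Map(function(nm, tt)
    data.frame(test = nm, statistic = tt$statistic, df = tt$df,
               p = tt$p_value, kind = tt$kind), names(tests), tests))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
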