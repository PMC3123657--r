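#' Duplicate subjects across event types and split follow-up into bands
#'
#' Implements the data-duplication device for joint competing-risks
#' modelling: each subject contributes one copy of their follow-up per
#' event type (stratum), and each copy is split into time bands fine
#' enough that every hazard — including the population hazard, which
#' jumps at attained-age and calendar-year boundaries — can be treated as
#' constant within a band.  The full survival likelihood then reduces to
#' a sum of Poisson-form terms, one per band.
#'
#' Band cut points are: a uniform grid of the given `width` (monthly by
#' default), every attained-age and attained-year integer crossing of the
#' subject, any extra `cut_times` (e.g. spline knots), and the subject's
#' follow-up time.  The population hazard is evaluated at the band
#' midpoint; by construction no band straddles an age or year boundary,
#' so the value is exact for the whole band.
#'
#' @param cohort A `crexhaz_cohort` (see [as_cohort()]).
#' @param J Number of event types (strata).  `J = 1` performs no
#'   duplication and is used for single-event fits.
#' @param lifetable A [lifetable], or `NULL`.  When supplied, every band
#'   gets the subject's expected hazard at the band midpoint (used by the
#'   likelihood only on the death stratum); follow-up outside the table's
#'   coverage is an error.  When `NULL` the expected hazard is 0.
#' @param width Uniform band width in years (default 1/12).
#' @param cut_times Extra cut times common to all subjects.
#' @return A data frame of class `band_table` with one row per
#'   (subject, stratum, band): columns `id`, `stratum`, `u0`, `u1`,
#'   `y = u1 - u0` (person-time), `tmid`, `d` (event indicator, 1 only on
#'   the final band of the stratum matching the subject's event type),
#'   `pop_haz`, demographics, and the cohort's covariate columns.
#' @export
duplicate_and_band <- function(cohort, J, lifetable = NULL, width = 1 / 12,
                               cut_times = numeric()) {
  stopifnot(inherits(cohort, "crexhaz_cohort"))
  J <- as.integer(J)
  if (J < 1L) stop("J must be at least 1")
  if (max(cohort$event_type) > J)
    stop("cohort contains event types above J = ", J)
  if (!is.finite(width) || width <= 0) stop("band width must be positive")
  covs <- attr(cohort, "covariates")
  n <- nrow(cohort)
  tol <- 1e-8

  breaks <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- cohort$time[i]
    b <- seq(0, ti, by = width)
    a0 <- floor(cohort$age[i]) + 1 - cohort$age[i]     # first age crossing
    y0 <- floor(cohort$year[i]) + 1 - cohort$year[i]   # first year crossing
    cr <- c(if (a0 < ti) seq(a0, ti, by = 1),
            if (y0 < ti) seq(y0, ti, by = 1))
    b <- sort(c(b, cr, cut_times[cut_times > 0 & cut_times < ti], ti))
    # drop near-duplicate cuts, always keeping the final endpoint ti
    keep <- c(diff(b) > tol, TRUE)
    b <- b[keep]
    if (b[1L] > tol) b <- c(0, b)
    breaks[[i]] <- b
  }
  nb <- lengths(breaks) - 1L
  if (any(nb < 1L)) stop("subject with no positive-width band")
  all_b <- unlist(breaks, use.names = FALSE)
  last <- cumsum(nb + 1L)
  u1 <- all_b[-c(1L, utils::head(last, -1L) + 1L)]     # drop each leading 0
  u0 <- all_b[-last]
  yy <- u1 - u0
  if (any(yy <= 0)) stop("non-positive band width produced; reduce cut ties")
  idx <- rep.int(seq_len(n), nb)                       # subject of each band
  tmid <- (u0 + u1) / 2
  lastband <- c(diff(idx) != 0L, TRUE)

  pop <- if (is.null(lifetable)) numeric(length(u0)) else
    expected_hazard(lifetable, cohort$age[idx], cohort$year[idx],
                    cohort$sex[idx], tmid)

  B <- length(u0)
  out <- data.frame(
    id = rep(cohort$id[idx], J),
    stratum = rep(seq_len(J), each = B),
    u0 = rep(u0, J), u1 = rep(u1, J), y = rep(yy, J),
    tmid = rep(tmid, J),
    d = as.numeric(rep(lastband, J) &
                     rep(cohort$event_type[idx], J) == rep(seq_len(J), each = B)),
    pop_haz = rep(pop, J),
    age = rep(cohort$age[idx], J),
    sex = rep(cohort$sex[idx], J),
    year = rep(cohort$year[idx], J),
    stringsAsFactors = FALSE)
  for (cv in covs) out[[cv]] <- rep(cohort[[cv]][idx], J)
  structure(out, J = J, covariates = covs, width = width,
            n_subjects = n, class = c("band_table", "data.frame"))
}

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("Band table: %d rows = %d subjects x %d strata, %.3g person-years/stratum\n",
              nrow(x), attr(x, "n_subjects"), attr(x, "J"),
              sum(x$y) / attr(x, "J")))
  invisible(as.data.frame(x))
}
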