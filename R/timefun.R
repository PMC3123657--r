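#' Specify a function of follow-up time
#'
#' A `time_spec` describes one of the candidate functional forms used for
#' the log baseline hazard and for time-dependent log hazard ratios
#' between event-specific hazards: a constant, a polynomial of degree 1-3,
#' or a cubic regression spline (a smooth piecewise cubic, continuous with
#' continuous first and second derivatives at the interior knots).  The
#' basis always contains the constant function, so the dimensions of the
#' six standard candidates are 1 (constant), 2 (linear), 3 (quadratic),
#' 4 (cubic), 5 (cubic spline, one interior knot), and 6 (cubic spline,
#' two interior knots).
#'
#' @param family One of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"cubic"`, `"cubic_spline"`.
#' @param knots Interior knots in years (cubic_spline only); strictly
#'   increasing, strictly inside the boundary knots.  Default: one knot at
#'   1 year, the conventional choice for cancers in which a large share of
#'   events occurs during the first year after diagnosis.
#' @param boundary Length-2 boundary knots.  `NULL` (default) means
#'   "resolve from the data at fit time" as `[0, max follow-up]`.
#' @return An object of class `time_spec`.
#' @seealso [build_basis()], [basis_dim()]
#' @export
time_spec <- function(family = c("cubic_spline", "constant", "linear",
                                 "quadratic", "cubic"),
                      knots = if (match.arg(family) == "cubic_spline") 1 else numeric(),
                      boundary = NULL) {
  family <- match.arg(family)
  knots <- as.numeric(knots)
  if (family != "cubic_spline" && length(knots))
    stop("knots are only meaningful for family = 'cubic_spline'")
  if (length(knots) && any(diff(knots) <= 0))
    stop("interior knots must be strictly increasing")
  if (!is.null(boundary)) {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || diff(boundary) <= 0)
      stop("boundary must be an increasing pair of times")
    if (length(knots) && (any(knots <= boundary[1L]) || any(knots >= boundary[2L])))
      stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(list(family = family, knots = knots, boundary = boundary),
            class = "time_spec")
}

#' @export
print.time_spec <- function(x, ...) {
  cat("time_spec:", x$family)
  if (length(x$knots)) cat(", knots at", paste(x$knots, collapse = ", "))
  if (!is.null(x$boundary))
    cat(sprintf(", boundary [%g, %g]", x$boundary[1L], x$boundary[2L]))
  cat(" (", basis_dim(x), " df)\n", sep = "")
  invisible(x)
}

#' Dimension of a time-function basis
#'
#' The number of free coefficients: `degree + 1` for polynomial families
#' (the constant counts as degree 0) and `number of interior knots + 4`
#' for a cubic regression spline including its constant term, so one
#' interior knot gives a 5-df function and two interior knots give 6 df.
#' The difference in dimension between a one-knot spline and a constant
#' (4) is the degrees of freedom of the likelihood-ratio test of a
#' constant versus a time-dependent between-event log hazard ratio.
#'
#' @param spec A [time_spec].
#' @return Integer dimension.
#' @export
basis_dim <- function(spec) {
  stopifnot(inherits(spec, "time_spec"))
  switch(spec$family,
         constant = 1L, linear = 2L, quadratic = 3L, cubic = 4L,
         cubic_spline = length(spec$knots) + 4L)
}

resolve_boundary <- function(spec, times) {
  if (!is.null(spec$boundary)) return(spec)
  if (length(unique(times)) < 2L)
    stop("cannot resolve boundary knots from fewer than 2 distinct times; ",
         "give the time_spec explicit boundary knots")
  spec$boundary <- c(min(0, min(times)), max(times))
  if (length(spec$knots) &&
      (any(spec$knots <= spec$boundary[1L]) || any(spec$knots >= spec$boundary[2L])))
    stop("interior knots fall outside the observed time range; ",
         "set boundary knots explicitly")
  spec
}

#' Evaluate a time-function basis
#'
#' Returns the design matrix of the basis functions at `times`.  For
#' `cubic_spline` this is a cubic B-spline basis including the constant
#' (evaluated with [splines::bs()] with an intercept), whose columns span
#' the space of cubic splines with the given interior knots; the basis
#' value and its first two derivatives are continuous at every interior
#' knot.  Times outside the boundary knots are an error (no silent
#' clamping or extrapolation).
#'
#' @param spec A [time_spec].  If its boundary knots are unresolved they
#'   are taken as `[min(0, times), max(times)]`, which requires at least
#'   two distinct times.
#' @param times Numeric vector of evaluation times (years).
#' @return Matrix with `length(times)` rows and [basis_dim()] columns.
#' @examples
#' B <- build_basis(time_spec("cubic_spline", knots = 1, boundary = c(0, 7)),
#'                  times = seq(0, 7, by = 0.5))
#' ncol(B)  # 5
#' @export
build_basis <- function(spec, times) {
  stopifnot(inherits(spec, "time_spec"), is.numeric(times))
  spec <- resolve_boundary(spec, times)
  b <- spec$boundary
  if (any(times < b[1L] - 1e-9 | times > b[2L] + 1e-9))
    stop(sprintf("times outside boundary knots [%g, %g]", b[1L], b[2L]))
  times <- pmin(pmax(times, b[1L]), b[2L])  # guard roundoff only
  out <- switch(
    spec$family,
    constant = matrix(1, length(times), 1L),
    linear = cbind(1, times),
    quadratic = cbind(1, times, times^2),
    cubic = cbind(1, times, times^2, times^3),
    cubic_spline = {
      m <- splines::bs(times, knots = spec$knots, degree = 3L,
                       intercept = TRUE, Boundary.knots = b)
      attributes(m)[c("degree", "knots", "Boundary.knots", "intercept",
                      "class")] <- NULL
      m
    })
  colnames(out) <- NULL
  out
}
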