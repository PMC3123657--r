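#' Population life table of expected mortality hazards
#'
#' A `lifetable` stores expected (population) mortality rates indexed by
#' completed age in years, calendar year, and sex.  Rates are deaths per
#' person-year and are treated as constant within each one-year age by
#' one-year period cell.  The grid must be complete over its declared
#' age/year ranges for both sexes present: competing-risks excess-hazard
#' fits look rates up for every person-time band and refuse to extrapolate.
#'
#' @param x A data frame with columns `age` (integer years), `year`
#'   (integer calendar year), `sex` (`"male"`/`"female"`), and `rate`
#'   (non-negative deaths per person-year).
#' @return An object of class `lifetable` with fields `rates` (a 3-d array
#'   age x year x sex), `ages`, `years`, and `sexes`.
#' @examples
#' lt <- lifetable(expand.grid(age = 0:5, year = 2000:2001,
#'                             sex = c("male", "female"),
#'                             KEEP.OUT.ATTRS = FALSE) |>
#'                 transform(rate = 0.01))
#' expected_hazard(lt, age_at_diag = 2.5, year_at_diag = 2000,
#'                 sex = "female", t = 1)
#' @export
lifetable <- function(x) {
  req <- c("age", "year", "sex", "rate")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "))
  x$age <- as.integer(x$age)
  x$year <- as.integer(x$year)
  x$sex <- as.character(x$sex)
  bad_sex <- setdiff(unique(x$sex), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex code(s) in rate table: ", paste(bad_sex, collapse = ", "))
  if (any(!is.finite(x$rate)))
    stop("non-finite rate at row ", which(!is.finite(x$rate))[1L])
  if (any(x$rate < 0)) {
    i <- which(x$rate < 0)[1L]
    stop(sprintf("negative rate at row %d (age=%d, year=%d, sex=%s)",
                 i, x$age[i], x$year[i], x$sex[i]))
  }
  key <- paste(x$age, x$year, x$sex)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate rate-table key (age=%d, year=%d, sex=%s)",
                 x$age[i], x$year[i], x$sex[i]))
  }
  ages <- min(x$age):max(x$age)
  years <- min(x$year):max(x$year)
  sexes <- sort(unique(x$sex))
  full <- expand.grid(age = ages, year = years, sex = sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$age, full$year, full$sex)
  hole <- !(fkey %in% key)
  if (any(hole)) {
    i <- which(hole)[1L]
    stop(sprintf("incomplete rate-table grid: missing (age=%d, year=%d, sex=%s)",
                 full$age[i], full$year[i], full$sex[i]))
  }
  rates <- array(NA_real_,
                 dim = c(length(ages), length(years), length(sexes)),
                 dimnames = list(age = ages, year = years, sex = sexes))
  rates[cbind(match(x$age, ages), match(x$year, years), match(x$sex, sexes))] <-
    x$rate
  structure(list(rates = rates, ages = ages, years = years, sexes = sexes),
            class = "lifetable")
}

#' Read a population rate table from CSV
#'
#' The file must have columns `age`, `year`, `sex` (`male`/`female`) and
#' `rate` (deaths per person-year).  The (age x year x sex) grid must be
#' complete over the ranges present in the file.
#'
#' @param path Path to a CSV file.
#' @return A [lifetable] object.
#' @export
read_ratetable <- function(path) {
  if (!file.exists(path)) stop("rate table file not found: ", path)
  lifetable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Population life table\n")
  cat(sprintf("  ages  %d-%d, years %d-%d, sexes: %s\n",
              min(x$ages), max(x$ages), min(x$years), max(x$years),
              paste(x$sexes, collapse = ", ")))
  cat(sprintf("  rates: %.3g-%.3g per person-year\n",
              min(x$rates), max(x$rates)))
  invisible(x)
}

#' Expected mortality hazard at an attained age and year
#'
#' Looks up the population rate for a subject diagnosed at age
#' `age_at_diag` in year `year_at_diag`, at time `t` since diagnosis.
#' Attained age and attained calendar year use the completed-years
#' convention, `floor(age_at_diag + t)` and `floor(year_at_diag + t)`, so
#' the returned rate is piecewise constant in `t` with jumps only at
#' age/year-boundary crossings.  Lookups outside the table's coverage are
#' an error; the rates are never extrapolated.
#'
#' All arguments are vectorised and recycled against each other.
#'
#' @param lt A [lifetable].
#' @param age_at_diag Age at diagnosis, years (may be fractional).
#' @param year_at_diag Calendar year at diagnosis (may be fractional).
#' @param sex `"male"` or `"female"`.
#' @param t Time since diagnosis in years.
#' @return Numeric vector of rates, deaths per person-year.
#' @export
expected_hazard <- function(lt, age_at_diag, year_at_diag, sex, t) {
  stopifnot(inherits(lt, "lifetable"))
  n <- max(length(age_at_diag), length(year_at_diag), length(sex), length(t))
  age_at_diag <- rep_len(age_at_diag, n)
  year_at_diag <- rep_len(year_at_diag, n)
  sex <- rep_len(as.character(sex), n)
  t <- rep_len(t, n)
  if (any(t < 0)) stop("t must be non-negative")
  a <- floor(age_at_diag + t)
  y <- floor(year_at_diag + t)
  ia <- match(a, lt$ages)
  iy <- match(y, lt$years)
  is <- match(sex, lt$sexes)
  bad <- which(is.na(ia) | is.na(iy) | is.na(is))
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(paste0("expected_hazard: attained (age=%d, year=%d, sex=%s) ",
                        "outside life-table coverage (ages %d-%d, years %d-%d)"),
                 a[b], y[b], sex[b], min(lt$ages), max(lt$ages),
                 min(lt$years), max(lt$years)))
  }
  lt$rates[cbind(ia, iy, is)]
}

#' Generate a synthetic life table with Gompertz-like adult mortality
#'
#' Produces a complete (age x year x sex) rate table whose log-rates
#' increase linearly with age, with a small log-linear calendar-year drift
#' and a cap on the oldest-age rates.  The defaults give rates of the
#' order observed in late-20th-century western European national life
#' tables (e.g. about 0.027 per person-year for a 70-year-old man and
#' about 0.016 for a 70-year-old woman in 2000).  This is a synthetic
#' stand-in for a national statistics table, intended for simulations and
#' examples.
#'
#' @param ages Integer vector of ages (default 0-109).
#' @param years Integer vector of calendar years.
#' @param intercept Named numeric, log-rate at age 0 for each sex.
#' @param slope Named numeric, increase of log-rate per year of age.
#' @param year_drift Change of log-rate per calendar year (relative to 2000).
#' @param max_rate Upper cap on rates, per person-year.
#' @return A [lifetable].
#' @export
make_lifetable <- function(ages = 0:109, years = 1988:2012,
                           intercept = c(male = -10.2, female = -10.9),
                           slope = c(male = 0.094, female = 0.097),
                           year_drift = -0.005, max_rate = 0.7) {
  g <- expand.grid(age = ages, year = years, sex = c("male", "female"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- pmin(exp(intercept[g$sex] + slope[g$sex] * g$age +
                       year_drift * (g$year - 2000)), max_rate)
  lifetable(g)
}
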