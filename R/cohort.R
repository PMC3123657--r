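#' Validate a competing-risks cohort table
#'
#' Checks the subject-level invariants of the competing-risks data
#' structure: one row per subject with follow-up time `time` > 0, status
#' `status` in {0, 1}, first-event type `event_type` in {0, ..., J} with
#' `status == 0` exactly when `event_type == 0`, demographics (`age`,
#' `sex`, `year`) for life-table lookup, and fully observed numeric
#' analysis covariates in the remaining columns.
#'
#' @param x A data frame.
#' @param covariates Character vector naming covariate columns; default:
#'   every column other than the core columns.
#' @return Character vector of human-readable violations, empty when the
#'   table is valid.  Each violation names the offending subject id.
#' @seealso [as_cohort()] which turns a valid table into a cohort object.
#' @export
validate_cohort <- function(x, covariates = NULL) {
  core <- c("id", "time", "status", "event_type", "age", "sex", "year")
  v <- character()
  miss <- setdiff(core, names(x))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (is.null(covariates)) covariates <- setdiff(names(x), core)
  bad <- function(i, what)
    sprintf("subject %s: %s", as.character(x$id[i]), what)
  add <- function(idx, what) if (length(idx)) c(v, vapply(idx, bad, "", what)) else v

  if (anyDuplicated(x$id))
    v <- c(v, paste("duplicated subject id:",
                    paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  v <- add(which(!is.finite(x$time) | x$time <= 0), "time must be finite and > 0")
  v <- add(which(!x$status %in% c(0, 1)), "status must be 0 or 1")
  et_ok <- is.finite(x$event_type) & x$event_type >= 0 &
    x$event_type == floor(x$event_type)
  v <- add(which(!et_ok), "event_type must be a non-negative integer")
  v <- add(which(et_ok & x$status == 0 & x$event_type != 0),
           "status = 0 requires event_type = 0")
  v <- add(which(et_ok & x$status == 1 & x$event_type == 0),
           "status = 1 requires event_type in 1..J")
  v <- add(which(!is.finite(x$age) | x$age < 0), "invalid age")
  v <- add(which(!as.character(x$sex) %in% c("male", "female")),
           "sex must be 'male' or 'female'")
  v <- add(which(!is.finite(x$year)), "invalid year")
  for (cv in covariates) {
    if (!is.numeric(x[[cv]])) {
      v <- c(v, sprintf("covariate '%s' must be numeric (expand factors to indicators)", cv))
      next
    }
    v <- add(which(!is.finite(x[[cv]])), sprintf("missing covariate '%s'", cv))
  }
  v
}

#' Construct a cohort object
#'
#' Validates `x` with [validate_cohort()] and, if it is clean, returns it
#' with class `crexhaz_cohort` and a `covariates` attribute naming the
#' analysis covariates (all non-core columns by default).
#'
#' @inheritParams validate_cohort
#' @return A `crexhaz_cohort` data frame.
#' @export
as_cohort <- function(x, covariates = NULL) {
  x <- as.data.frame(x)
  v <- validate_cohort(x, covariates)
  if (length(v))
    stop("invalid cohort:\n  ", paste(utils::head(v, 10L), collapse = "\n  "),
         if (length(v) > 10L) sprintf("\n  ... and %d more", length(v) - 10L))
  core <- c("id", "time", "status", "event_type", "age", "sex", "year")
  if (is.null(covariates)) covariates <- setdiff(names(x), core)
  x$sex <- as.character(x$sex)
  structure(x, covariates = covariates, class = c("crexhaz_cohort", "data.frame"))
}

#' @export
print.crexhaz_cohort <- function(x, ...) {
  J <- max(x$event_type)
  cat(sprintf("Competing-risks cohort: %d subjects, %d event type(s)\n",
              nrow(x), J))
  tab <- table(factor(x$event_type, levels = 0:J))
  cat("  events: ", paste(sprintf("type %s: %d", names(tab), tab),
                          collapse = ", "), "\n", sep = "")
  cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  invisible(as.data.frame(x))
}

#' Read a cohort from CSV
#'
#' Columns: `id, time, status, event_type, age, sex, year` plus numeric
#' covariate columns.
#'
#' @param path CSV file path.
#' @param covariates Optional character vector of covariate columns.
#' @return A `crexhaz_cohort`.
#' @export
read_cohort <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  as_cohort(utils::read.csv(path, stringsAsFactors = FALSE), covariates)
}

#' Apply registry-style exclusion rules
#'
#' Removes records with unknown disease stage and records metastatic at
#' diagnosis (stage IV), the standard exclusions when distant metastasis
#' is itself one of the events under study.  Records matching an unknown
#' stage code (or a missing stage) are counted under `unknown_stage`;
#' among the remainder, records matching a metastatic code are counted
#' under `synchronous_metastasis`.
#'
#' @param x A raw data frame containing a stage column.
#' @param stage_col Name of the stage column (default `"stage"`).
#' @param unknown_codes Stage codes treated as unknown; `NA` always is.
#' @param metastatic_codes Stage codes treated as metastatic at diagnosis.
#' @param expand_stage If `TRUE` (default), replace the stage column of
#'   the retained records by treatment-coded indicator covariates (one per
#'   remaining non-reference stage level, reference = first level) and
#'   return a validated cohort; otherwise return the retained raw table.
#' @return A list with elements `data` (retained records, a
#'   `crexhaz_cohort` when `expand_stage = TRUE`) and `counts` (named
#'   integer vector of per-rule exclusion counts).
#' @examples
#' raw <- simulate_registry_cohort(n = 120, n_unknown_stage = 6,
#'                                 n_stage4 = 4, seed = 1)
#' apply_exclusions(raw)$counts
#' @export
apply_exclusions <- function(x, stage_col = "stage",
                             unknown_codes = c("unknown", "9", "X"),
                             metastatic_codes = c("IV", "4"),
                             expand_stage = TRUE) {
  if (!stage_col %in% names(x))
    stop("no stage column '", stage_col, "' in the data")
  st <- as.character(x[[stage_col]])
  unk <- is.na(st) | st %in% unknown_codes
  met <- !unk & st %in% metastatic_codes
  counts <- c(unknown_stage = sum(unk), synchronous_metastasis = sum(met))
  keep <- x[!(unk | met), , drop = FALSE]
  if (expand_stage && nrow(keep)) {
    lev <- sort(unique(as.character(keep[[stage_col]])))
    for (l in lev[-1L])
      keep[[paste0(stage_col, l)]] <- as.numeric(keep[[stage_col]] == l)
    keep[[stage_col]] <- NULL
    keep <- as_cohort(keep)
  } else if (expand_stage) {
    keep[[stage_col]] <- NULL
  }
  list(data = keep, counts = counts)
}
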