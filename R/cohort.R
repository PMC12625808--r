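## Subject-level data model: one row per subject, arm-coded treatment,
## first-nonfatal-event time (NA if never observed), last known follow-up,
## and a death flag saying whether follow-up ended in death.

#' Canonical cohort column names
#'
#' The six roles every cohort must provide. Source files with other headers
#' are handled through the `column_map` argument of [read_cohort()].
#'
#' @format Character vector of length 6.
#' @export
cohort_columns <- c(
  "subject_id", "arm", "event_time", "event_observed",
  "followup_time", "death_observed"
)

#' Coerce a data frame to a validated cohort
#'
#' A cohort holds one record per subject: an opaque `subject_id`, the
#' randomized arm `arm` (0 = placebo, 1 = active), the time of the first
#' nonfatal event `event_time` (`NA` when no event was observed) with its
#' indicator `event_observed`, the last known follow-up time `followup_time`
#' (`min(death, censoring, administrative cap)`), and `death_observed`
#' indicating whether follow-up ended in death rather than censoring.
#'
#' Times are unit-agnostic positive reals; no date handling is attempted.
#' Extra columns (for example the latent draws attached by
#' [simulate_cohort()]) are carried along untouched.
#'
#' @param x A data frame containing at least the columns in [cohort_columns].
#'   Indicator columns accept logicals, 0/1, or the strings
#'   `"true"`/`"false"` in any case.
#' @param validate If `TRUE` (default), stop with all violations listed when
#'   the cohort is invalid.
#' @return An object of class `ppsh_cohort` (a data frame).
#' @seealso [validate_cohort()], [read_cohort()]
#' @export
#' @examples
#' as_cohort(data.frame(
#'   subject_id = c("a", "b"), arm = c(0, 1),
#'   event_time = c(0.4, NA), event_observed = c(1, 0),
#'   followup_time = c(1.2, 2.0), death_observed = c(0, 1)
#' ))
as_cohort <- function(x, validate = TRUE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols)) {
    stop("missing required cohort column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    subject_id     = as.character(x$subject_id),
    arm            = .parse_arm(x$arm),
    event_time     = suppressWarnings(as.numeric(x$event_time)),
    event_observed = .parse_indicator(x$event_observed),
    followup_time  = suppressWarnings(as.numeric(x$followup_time)),
    death_observed = .parse_indicator(x$death_observed),
    stringsAsFactors = FALSE
  )
  for (nm in setdiff(names(x), cohort_columns)) out[[nm]] <- x[[nm]]
  rownames(out) <- NULL
  class(out) <- c("ppsh_cohort", "data.frame")
  if (validate) {
    v <- validate_cohort(out)
    if (length(v)) {
      stop("invalid cohort:\n", paste0("  - ", v, collapse = "\n"))
    }
  }
  out
}

.parse_arm <- function(a) {
  if (is.character(a)) suppressWarnings(as.numeric(a)) else as.numeric(a)
}

.parse_indicator <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x %in% 0] <- FALSE
    out[x %in% 1] <- TRUE
    return(out)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true")] <- TRUE
  out[lx %in% c("0", "false")] <- FALSE
  out
}

#' List invariant violations in a cohort
#'
#' Checks every record-level invariant (valid arm code, positive follow-up,
#' event time present exactly when an event is flagged and lying in
#' `(0, followup_time]`) plus cohort-level uniqueness of subject ids.
#' Violations are returned, not raised, so callers can report them all at
#' once.
#'
#' @param cohort A `ppsh_cohort` or data frame with the canonical columns.
#' @return Character vector of human-readable violations; empty when the
#'   cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  v <- character()
  id <- as.character(cohort$subject_id)
  if (anyNA(id) || any(!nzchar(id))) {
    v <- c(v, sprintf("record %s: missing subject_id",
                      paste(which(is.na(id) | !nzchar(id)), collapse = ", ")))
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    v <- c(v, sprintf("duplicate subject_id: %s", paste(dup, collapse = ", ")))
  }
  lab <- ifelse(is.na(id) | !nzchar(id), paste0("record ", seq_along(id)),
                paste0("subject '", id, "'"))
  bad <- is.na(cohort$arm) | !(cohort$arm %in% c(0, 1))
  v <- c(v, sprintf("%s: arm must be 0 or 1", lab[bad]))
  bad <- is.na(cohort$followup_time) | !is.finite(cohort$followup_time) |
    cohort$followup_time <= 0
  v <- c(v, sprintf("%s: followup_time must be a positive number", lab[bad]))
  for (col in c("event_observed", "death_observed")) {
    bad <- is.na(cohort[[col]])
    v <- c(v, sprintf("%s: %s must be 0/1 or true/false", lab[bad], col))
  }
  ev <- cohort$event_observed
  ev[is.na(ev)] <- FALSE
  bad <- ev & is.na(cohort$event_time)
  v <- c(v, sprintf("%s: event_observed but event_time is missing", lab[bad]))
  ok_fu <- !is.na(cohort$followup_time)
  bad <- ev & !is.na(cohort$event_time) &
    (cohort$event_time <= 0 |
       (ok_fu & cohort$event_time > cohort$followup_time))
  v <- c(v, sprintf(
    "%s: event_time must satisfy 0 < event_time <= followup_time", lab[bad]))
  bad <- !ev & !is.na(cohort$event_time)
  v <- c(v, sprintf("%s: event_time present but event_observed is false",
                    lab[bad]))
  v
}

#' Distinct observed nonfatal event times
#'
#' The strictly increasing set of first-nonfatal-event times observed in the
#' cohort; the support of the partial likelihood.
#'
#' @param cohort A validated `ppsh_cohort`.
#' @return Sorted numeric vector (possibly empty).
#' @export
event_times <- function(cohort) {
  sort(unique(cohort$event_time[cohort$event_observed]))
}

#' Read a cohort from delimited text
#'
#' Reads a header-ed delimited file (CSV by default) into a validated cohort.
#' Source files with arbitrary column headers are supported through
#' `column_map`, a mapping from canonical role (see [cohort_columns]) to the
#' source header; it can be given as a named character vector or as the path
#' to a YAML/JSON file of `role: header` pairs. Missing event times are
#' encoded as empty fields; indicators accept `0/1/true/false`.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector (`canonical = source`) or path to
#'   a YAML file with the same content. `NULL` expects canonical headers.
#' @param sep Field separator, `","` by default (use `"\t"` for TSV).
#' @return A `ppsh_cohort`, rows in file order.
#' @export
read_cohort <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map)) {
    column_map <- unlist(yaml::read_yaml(column_map))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- vapply(column_map, as.character, "")
    unmapped <- setdiff(cohort_columns, names(column_map))
    if (length(unmapped)) {
      stop("column_map leaves required role(s) unmapped: ",
           paste(unmapped, collapse = ", "))
    }
    absent <- setdiff(unname(column_map[cohort_columns]), names(df))
    if (length(absent)) {
      stop("mapped column(s) not present in file: ",
           paste(absent, collapse = ", "))
    }
    mapped <- df[unname(column_map[cohort_columns])]
    names(mapped) <- cohort_columns
    df <- cbind(mapped, df[setdiff(names(df), unname(column_map))])
  }
  as_cohort(df)
}

#' Write a cohort to delimited text
#'
#' Writes the six canonical columns with a canonical header. Times are
#' serialized at full double precision so that [read_cohort()] inverts the
#' write exactly, and rewriting a re-read file is byte-identical. Missing
#' event times become empty fields; indicators are written as 0/1.
#'
#' @param cohort A validated `ppsh_cohort`.
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  v <- validate_cohort(cohort)
  if (length(v)) stop("refusing to write invalid cohort:\n",
                      paste0("  - ", v, collapse = "\n"))
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  body <- paste(
    cohort$subject_id,
    sprintf("%d", as.integer(cohort$arm)),
    num(cohort$event_time),
    as.integer(cohort$event_observed),
    num(cohort$followup_time),
    as.integer(cohort$death_observed),
    sep = sep
  )
  con <- file(path, open = "wb") # fixed EOL across platforms
  on.exit(close(con))
  writeLines(c(paste(cohort_columns, collapse = sep), body), con, sep = "\n")
  invisible(path)
}

#' @export
print.ppsh_cohort <- function(x, ...) {
  cat(sprintf(
    "Semi-competing-risks cohort: %d subjects (%d placebo / %d active)\n",
    nrow(x), sum(x$arm == 0), sum(x$arm == 1)))
  cat(sprintf("  nonfatal events: %d   deaths: %d\n",
              sum(x$event_observed), sum(x$death_observed)))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
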