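# Cohort data model: per-patient records, derived variables, delimited I/O.

#' @keywords internal
HISTORY_FLAGS <- c("hypertension", "stroke", "chd", "dm", "af")

#' @keywords internal
CHANGE_LEVELS <- c("disappear", "keep", "appear")

#' @keywords internal
BASE_COLUMNS <- c("id", "age", "sex", "hx_hypertension", "hx_stroke",
                  "hx_chd", "hx_dm", "hx_af", "onset_hours",
                  "nihss_d1", "nihss_d3", "bi_d90")

#' Derive the dichotomous 90-day outcome from the Barthel Index
#'
#' Good recovery is a day-90 Barthel Index (BI) of 90 or higher, i.e. near
#' full functional independence; everything below 90 is poor recovery.
#'
#' @param bi_day90 Integer vector of day-90 Barthel Index values in
#'   `[0, 100]`.
#' @return Character vector with values `"good"` or `"poor"`.
#' @examples
#' derive_outcome(c(90, 100, 89))
#' @export
derive_outcome <- function(bi_day90) {
  bi <- as.numeric(bi_day90)
  if (any(is.na(bi)) || any(bi < 0) || any(bi > 100)) {
    stop("bi_day90 must lie in [0, 100] with no missing values", call. = FALSE)
  }
  ifelse(bi >= 90, "good", "poor")
}

#' Early change in stroke severity
#'
#' The day-3 minus day-1 difference in NIHSS; negative values mean early
#' neurological improvement.
#'
#' @param nihss_day1,nihss_day3 Integer NIHSS scores in `[0, 42]`.
#' @return Integer vector of differences (day 3 minus day 1).
#' @export
derive_delta_nihss <- function(nihss_day1, nihss_day3) {
  check_nihss(nihss_day1, "nihss_day1")
  check_nihss(nihss_day3, "nihss_day3")
  as.integer(nihss_day3) - as.integer(nihss_day1)
}

check_nihss <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 42) || any(x != round(x))) {
    stop(what, " must be integer in [0, 42]", call. = FALSE)
  }
  invisible(x)
}

#' Ternary day-1 to day-3 symptom change status
#'
#' A symptom present on day 1 but gone by day 3 has *disappeared*; one absent
#' on day 1 but present on day 3 has *appeared*; otherwise (present both days
#' or absent both days) its status is *keep*.
#'
#' @param present_day1,present_day3 Logical (or 0/1) vectors of symptom
#'   presence on days 1 and 3.
#' @return Character vector with values `"appear"`, `"keep"`, `"disappear"`.
#' @export
derive_change_status <- function(present_day1, present_day3) {
  p1 <- as.logical(present_day1)
  p3 <- as.logical(present_day3)
  if (any(is.na(p1)) || any(is.na(p3))) {
    stop("symptom presence must be non-missing logical/0-1", call. = FALSE)
  }
  ifelse(p1 & !p3, "disappear", ifelse(!p1 & p3, "appear", "keep"))
}

#' Ordinal coding of a change status
#'
#' disappear = 0, keep = 1, appear = 2.  This is the coding used both for the
#' single-coefficient change terms in the logistic model and for the category
#' index of the change items of the scale.
#'
#' @param status Character vector of `"disappear"`, `"keep"`, `"appear"`.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
change_code <- function(status) {
  code <- match(status, CHANGE_LEVELS) - 1L
  if (any(is.na(code))) stop("unknown change status", call. = FALSE)
  code
}

#' Construct a validated cohort table
#'
#' A cohort table is a data frame with one row per patient, the fixed
#' demographic/severity columns and one `sym_<name>_d1` / `sym_<name>_d3`
#' 0/1 pair per panel symptom, carrying the symptom panel as an attribute.
#'
#' @param data Data frame with the columns described in [read_cohort()].
#' @param panel Character vector of symptom names; if `NULL`, inferred from
#'   the `sym_*_d1` columns (order of appearance preserved).
#' @return An object of class `cohort_table` (a data frame).
#' @export
cohort_table <- function(data, panel = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(panel)) panel <- infer_panel(names(data))
  validate_cohort(data, panel)
  attr(data, "panel") <- panel
  class(data) <- c("cohort_table", "data.frame")
  data
}

infer_panel <- function(cols) {
  d1 <- grep("^sym_(.+)_d1$", cols, value = TRUE)
  sub("^sym_(.+)_d1$", "\\1", d1)
}

#' Symptom panel of a cohort
#' @param cohort A `cohort_table`.
#' @return Character vector of symptom names.
#' @export
cohort_panel <- function(cohort) attr(cohort, "panel")

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort of %d patients; symptom panel of %d: %s\n",
              nrow(x), length(cohort_panel(x)),
              paste(utils::head(cohort_panel(x), 5), collapse = ", ")))
  NextMethod()
}

validate_cohort <- function(data, panel) {
  missing_cols <- setdiff(BASE_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sym_cols <- as.vector(rbind(paste0("sym_", panel, "_d1"),
                              paste0("sym_", panel, "_d3")))
  missing_sym <- setdiff(sym_cols, names(data))
  if (length(missing_sym)) {
    stop("cohort is missing symptom column(s): ",
         paste(missing_sym, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) return(invisible(data))
  if (anyDuplicated(data$id)) {
    stop("duplicate patient id(s): ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  check_range <- function(col, lo, hi, integer = FALSE) {
    x <- data[[col]]
    bad <- is.na(x) | x < lo | x > hi
    if (integer) bad <- bad | x != round(x)
    if (any(bad)) {
      stop(sprintf("column %s: invalid value in row(s) %s (must be %sin [%s, %s])",
                   col, paste(utils::head(which(bad), 5), collapse = ", "),
                   if (integer) "integer " else "", lo, hi), call. = FALSE)
    }
  }
  check_range("age", 0 + 1e-9, 130)
  check_range("onset_hours", 0, 24)
  check_range("nihss_d1", 0, 42, integer = TRUE)
  check_range("nihss_d3", 0, 42, integer = TRUE)
  check_range("bi_d90", 0, 100, integer = TRUE)
  if (!all(data$sex %in% c("male", "female"))) {
    stop("column sex: values must be 'male' or 'female'", call. = FALSE)
  }
  for (col in c(paste0("hx_", HISTORY_FLAGS), sym_cols)) {
    check_range(col, 0, 1, integer = TRUE)
  }
  invisible(data)
}

#' Read a cohort from a delimited text file
#'
#' Expects UTF-8 comma-separated text with one header row and the columns
#' `id, age, sex, hx_hypertension, hx_stroke, hx_chd, hx_dm, hx_af,
#' onset_hours, nihss_d1, nihss_d3, bi_d90`, followed by a
#' `sym_<name>_d1` / `sym_<name>_d3` 0/1 pair for every panel symptom.
#' The file is validated on load (ranges, duplicate ids, paired symptom
#' columns); row order is preserved.
#'
#' @param path Path to the file.
#' @param panel Optional character vector restricting/ordering the symptom
#'   panel; default infers it from the header.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(data)) data$id <- as.character(data$id)
  cohort_table(data, panel = panel)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` returns a
#' table equal field-for-field to `x`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
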