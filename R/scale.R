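# The 8-item weighted-point prognostic scale: definition, application,
# serialization.

#' Define one item of a prognostic scale
#'
#' An item maps a patient-derived value to a category index and assigns each
#' category a number of points (multiples of 0.5).  Three kinds are
#' supported:
#' \describe{
#'   \item{threshold}{a continuous/integer variable binned against sorted
#'     thresholds with `<=` boundaries, as produced by [grow_thresholds()];}
#'   \item{binary}{a 0/1 variable (history flag or day-1 symptom), category
#'     0 = absent, 1 = present;}
#'   \item{change}{the day-1 to day-3 change status of a panel symptom,
#'     categories ordered disappear, keep, appear.}
#' }
#'
#' @param name Item name.
#' @param weight Nonnegative weight; the points of category `k` are
#'   `weight * k`.
#' @param kind One of `"threshold"`, `"binary"`, `"change"`.
#' @param variable Cohort column the item reads (`"age"`, `"nihss_d1"`,
#'   `"delta_nihss"`, an `hx_*`/`sym_*_d1` column) or, for change items, the
#'   bare symptom name.
#' @param points Numeric vector of points per category, each a multiple of
#'   0.5, in category order.
#' @param thresholds For threshold items, strictly increasing cut values.
#' @return An object of class `scale_item`.
#' @export
scale_item <- function(name, weight, kind, variable, points,
                       thresholds = NULL) {
  kind <- match.arg(kind, c("threshold", "binary", "change"))
  if (length(points) < 1 || any(points < 0)) {
    stop("item '", name, "': points must be a nonempty nonnegative vector",
         call. = FALSE)
  }
  if (any(abs(points * 2 - round(points * 2)) > 1e-9)) {
    stop("item '", name, "': points must be multiples of 0.5", call. = FALSE)
  }
  if (kind == "threshold") {
    if (is.null(thresholds) || is.unsorted(thresholds, strictly = TRUE)) {
      stop("item '", name, "': thresholds must be strictly increasing",
           call. = FALSE)
    }
    if (length(points) != length(thresholds) + 1) {
      stop("item '", name, "': need one points entry per interval",
           call. = FALSE)
    }
  }
  if (kind == "binary" && length(points) != 2) {
    stop("item '", name, "': binary items need exactly 2 point values",
         call. = FALSE)
  }
  if (kind == "change" && length(points) != 3) {
    stop("item '", name, "': change items need exactly 3 point values ",
         "(disappear, keep, appear)", call. = FALSE)
  }
  structure(list(name = name, weight = weight, kind = kind,
                 variable = variable, points = as.numeric(points),
                 thresholds = if (!is.null(thresholds)) as.numeric(thresholds)),
            class = "scale_item")
}

#' Assemble a scale definition
#'
#' @param items List of [scale_item()]s.
#' @param cutoff Decision threshold on the total score: a total strictly
#'   greater than `cutoff` predicts poor recovery.
#' @param strict If `TRUE`, require exactly 8 items (the published
#'   instrument's structure).
#' @return An object of class `scale_definition` with fields `items`,
#'   `cutoff` and `max_total` (sum of per-item maxima).
#' @export
scale_definition <- function(items, cutoff, strict = FALSE) {
  if (!length(items) || !all(vapply(items, inherits, TRUE, "scale_item"))) {
    stop("items must be a nonempty list of scale_item objects", call. = FALSE)
  }
  if (strict && length(items) != 8) {
    stop("strict scale definition requires exactly 8 items, got ",
         length(items), call. = FALSE)
  }
  max_total <- sum(vapply(items, function(it) max(it$points), 0))
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= max_total) {
    stop("cutoff must lie strictly inside (0, max_total)", call. = FALSE)
  }
  structure(list(items = items, cutoff = cutoff, max_total = max_total),
            class = "scale_definition")
}

#' The published 8-item prognostic scale
#'
#' Returns the default scale: age (threshold 56.44 years), history of
#' diabetes, anxiety on day 1, NIHSS on day 1 (<=2 / 3--6 / >=7),
#' irritability on day 1, day-1 to day-3 NIHSS change (<= -1 / > -1), and
#' the day-1 to day-3 change status of circumrotating (vertigo) and
#' tinnitus.  Maximum total 16.5 points; cutoff 9.5 (a total > 9.5 predicts
#' poor 90-day recovery).
#'
#' @return A [scale_definition()] with 8 items.
#' @examples
#' sc <- default_scale()
#' sc$max_total
#' sc$cutoff
#' @export
default_scale <- function() {
  items <- list(
    scale_item("age_degree", 1, "threshold", "age",
               points = c(0, 1), thresholds = 56.44),
    scale_item("history_dm", 1, "binary", "hx_dm", points = c(0, 1)),
    scale_item("anxiety_day1", 1, "binary", "sym_anxiety_d1",
               points = c(0, 1)),
    scale_item("nihss_day1_degree", 1, "threshold", "nihss_d1",
               points = c(0, 1, 2), thresholds = c(2, 6)),
    scale_item("irritability_day1", 1.5, "binary", "sym_irritability_d1",
               points = c(0, 1.5)),
    scale_item("delta_nihss_degree", 1, "threshold", "delta_nihss",
               points = c(0, 1), thresholds = -1),
    scale_item("circumrotating_change", 2, "change", "circumrotating",
               points = c(0, 2, 4)),
    scale_item("tinnitus_change", 2.5, "change", "tinnitus",
               points = c(0, 2.5, 5))
  )
  scale_definition(items, cutoff = 9.5, strict = TRUE)
}

#' Published category codings of the continuous scale predictors
#'
#' The fixed discretizations the default scale uses: age at 56.44 years,
#' day-1 NIHSS at 2 and 6 (three categories), NIHSS change at -1.  Useful
#' for building the category-coded design matrix of the logistic stage
#' without re-deriving cutpoints.
#'
#' @return Named list of threshold vectors keyed by `age`, `nihss_d1`,
#'   `delta_nihss`.
#' @export
published_discretizations <- function() {
  list(age = 56.44, nihss_d1 = c(2, 6), delta_nihss = -1)
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("Prognostic scale: %d items, max total %.1f, cutoff %.1f\n",
              length(x$items), x$max_total, x$cutoff))
  for (it in x$items) {
    cat(sprintf("  %-24s [%s on %s] points: %s\n", it$name, it$kind,
                it$variable, paste(format(it$points), collapse = "/")))
  }
  invisible(x)
}

# Category index (0-based) of one item for every row of a cohort.
item_category <- function(item, cohort, absent_pair_policy = "keep") {
  switch(item$kind,
    threshold = {
      value <- if (identical(item$variable, "delta_nihss")) {
        derive_delta_nihss(cohort$nihss_d1, cohort$nihss_d3)
      } else {
        get_column(cohort, item$variable, item$name)
      }
      bin_variable(value, item$thresholds)
    },
    binary = as.integer(get_column(cohort, item$variable, item$name) != 0),
    change = {
      d1 <- get_column(cohort, paste0("sym_", item$variable, "_d1"), item$name)
      d3 <- get_column(cohort, paste0("sym_", item$variable, "_d3"), item$name)
      change_code(derive_change_status(d1, d3))
    }
  )
}

get_column <- function(cohort, col, item_name) {
  if (!col %in% names(cohort)) {
    stop("item '", item_name, "': cohort lacks required column '", col, "'",
         call. = FALSE)
  }
  cohort[[col]]
}

# Points of one item for every row, honoring the absent-pair policy for
# change items (a symptom absent on both days is literally "keep"; the
# alternative policy scores such pairs 0).
item_points <- function(item, cohort, absent_pair_policy = "keep") {
  cat_idx <- item_category(item, cohort)
  pts <- item$points[cat_idx + 1L]
  if (item$kind == "change" && absent_pair_policy == "zero") {
    d1 <- cohort[[paste0("sym_", item$variable, "_d1")]]
    d3 <- cohort[[paste0("sym_", item$variable, "_d3")]]
    pts[d1 == 0 & d3 == 0] <- 0
  }
  pts
}

#' Score every patient of a cohort
#'
#' Applies each item's categorizer, looks up the assigned points, sums them,
#' and classifies against the cutoff.
#'
#' @param scale A [scale_definition()].
#' @param cohort A [cohort_table()] (or data frame with the needed columns).
#' @param absent_pair_policy How change items score a symptom absent on both
#'   days: `"keep"` (the literal reading: such pairs take the keep points,
#'   the default) or `"zero"`.
#' @return Data frame with `id`, one points column per item, `total`, and
#'   `predicted` (`"good"`/`"poor"`).
#' @export
score_cohort <- function(scale, cohort,
                         absent_pair_policy = c("keep", "zero")) {
  absent_pair_policy <- match.arg(absent_pair_policy)
  stopifnot(inherits(scale, "scale_definition"))
  per_item <- lapply(scale$items, item_points, cohort = cohort,
                     absent_pair_policy = absent_pair_policy)
  names(per_item) <- vapply(scale$items, `[[`, "", "name")
  total <- Reduce(`+`, per_item)
  out <- data.frame(id = if ("id" %in% names(cohort)) cohort$id
                         else seq_len(nrow(cohort)),
                    stringsAsFactors = FALSE)
  out[names(per_item)] <- per_item
  out$total <- total
  out$predicted <- classify_score(total, scale$cutoff)
  out
}

#' Score a single patient
#'
#' @inheritParams score_cohort
#' @param record One-row data frame or named list with the fields the
#'   scale's items need.
#' @return List with `per_item` (named numeric), `total` and `predicted`.
#' @export
score_patient <- function(scale, record,
                          absent_pair_policy = c("keep", "zero")) {
  absent_pair_policy <- match.arg(absent_pair_policy)
  rec <- as.data.frame(as.list(record), stringsAsFactors = FALSE)
  scored <- score_cohort(scale, rec, absent_pair_policy = absent_pair_policy)
  item_names <- vapply(scale$items, `[[`, "", "name")
  list(per_item = unlist(scored[1, item_names]),
       total = scored$total[1], predicted = scored$predicted[1])
}

#' Classify a total score against a cutoff
#'
#' Strictly-greater rule: a total higher than the cutoff predicts poor
#' recovery; a total equal to the cutoff predicts good.
#'
#' @param total Numeric vector of total scores.
#' @param cutoff Decision threshold.
#' @return Character vector, `"poor"` where `total > cutoff`, else `"good"`.
#' @export
classify_score <- function(total, cutoff) {
  stopifnot(is.finite(cutoff))
  ifelse(total > cutoff, "poor", "good")
}

#' Enumerate all attainable total scores of a scale
#'
#' Cartesian product of every item's point values; used to verify the score
#' range by brute force.
#'
#' @param scale A [scale_definition()].
#' @return Numeric vector of totals, one per category combination.
#' @export
enumerate_totals <- function(scale) {
  grids <- lapply(scale$items, `[[`, "points")
  rowSums(as.matrix(expand.grid(grids)))
}

#' Save a scale definition as JSON
#'
#' @param scale A [scale_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scale <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  obj <- list(
    cutoff = scale$cutoff,
    items = lapply(scale$items, function(it) {
      x <- list(name = it$name, weight = it$weight, kind = it$kind,
                variable = it$variable, points = it$points)
      if (!is.null(it$thresholds)) x$thresholds <- it$thresholds
      x
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a scale definition from JSON
#'
#' @param path Path to a file written by [save_scale()] (or hand-authored in
#'   the same shape).
#' @param strict Require the published 8-item structure.
#' @return A [scale_definition()].
#' @export
load_scale <- function(path, strict = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$items) || is.null(obj$cutoff)) {
    stop("scale file must contain 'items' and 'cutoff'", call. = FALSE)
  }
  items <- lapply(obj$items, function(x) {
    scale_item(x$name, x$weight, x$kind, x$variable,
               points = unlist(x$points),
               thresholds = if (!is.null(x$thresholds)) unlist(x$thresholds))
  })
  scale_definition(items, cutoff = obj$cutoff, strict = strict)
}
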