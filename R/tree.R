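# Classification-tree cutpoint discovery (CART-style, Gini impurity) used
# to turn continuous predictors -- age, day-1 NIHSS, NIHSS change -- into
# the scale's ordered categories.

gini <- function(y) {
  if (!length(y)) return(0)
  p <- mean(y)
  2 * p * (1 - p)
}

#' Best single binary split of a continuous predictor
#'
#' Exhaustive search over the midpoints between consecutive distinct sorted
#' values; returns the split maximizing the Gini impurity decrease, ties
#' broken toward the smallest threshold.  Deterministic.
#'
#' @param values Numeric predictor vector.
#' @param labels Binary outcome vector (0/1, logical, or two levels).
#' @param min_leaf Minimum observations on each side of the split.
#' @return List of class `split_result`: `threshold` (NA if no admissible
#'   split), `gain`, `impurity_parent`, `impurity_children` (weighted),
#'   `left_n`, `right_n`.
#' @export
best_split <- function(values, labels, min_leaf = 1) {
  y <- as_binary_labels(labels)
  n <- length(values)
  stopifnot(length(y) == n)
  no_split <- structure(
    list(threshold = NA_real_, gain = 0, impurity_parent = gini(y),
         impurity_children = gini(y), left_n = 0L, right_n = n),
    class = "split_result")
  if (n < 2 * min_leaf || length(unique(y)) < 2) return(no_split)
  ord <- order(values)
  v <- values[ord]
  ys <- y[ord]
  # candidate cut after position i (1..n-1) where v[i] < v[i+1]
  cum_pos <- cumsum(ys)
  i <- seq_len(n - 1)
  ok <- (v[i] < v[i + 1]) & (i >= min_leaf) & (n - i >= min_leaf)
  if (!any(ok)) return(no_split)
  i <- i[ok]
  nl <- i
  nr <- n - i
  pl <- cum_pos[i] / nl
  pr <- (cum_pos[n] - cum_pos[i]) / nr
  child_imp <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  parent_imp <- gini(y)
  gain <- parent_imp - child_imp
  best <- which(gain >= max(gain) - 1e-12)[1]  # smallest threshold among ties
  if (gain[best] <= 1e-12) return(no_split)
  structure(
    list(threshold = (v[i[best]] + v[i[best] + 1]) / 2,
         gain = gain[best], impurity_parent = parent_imp,
         impurity_children = child_imp[best],
         left_n = as.integer(nl[best]), right_n = as.integer(nr[best])),
    class = "split_result")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1",
                                        call. = FALSE)
    return(as.integer(labels))
  }
  u <- sort(unique(as.character(labels)))
  if (length(u) > 2) stop("labels must be binary", call. = FALSE)
  as.integer(as.character(labels) == u[length(u)])
}

#' Recursive cutpoint discovery for one predictor
#'
#' Recursively applies [best_split()] to the two sides of each accepted
#' split down to `max_depth`, and returns the sorted union of thresholds.
#' `max_depth = 1` yields at most one threshold (a two-category coding, as
#' for age and the NIHSS change); `max_depth = 2` at most three, which
#' `max_thresholds` can prune to the splits with the largest gains (the
#' three-category day-1 NIHSS coding keeps the top two).
#'
#' @inheritParams best_split
#' @param max_depth Maximum recursion depth (0 = no thresholds).
#' @param max_thresholds Optional cap: keep only this many thresholds,
#'   chosen by decreasing gain.
#' @param variable Optional variable name carried into the result.
#' @return List of class `discretization`: `variable`, `thresholds`
#'   (sorted), `gains` (in threshold order), `labels` (interval labels).
#' @export
grow_thresholds <- function(values, labels, max_depth = 1, min_leaf = 20,
                            max_thresholds = NULL, variable = NULL) {
  y <- as_binary_labels(labels)
  acc <- list()
  recurse <- function(idx, depth) {
    if (depth > max_depth) return()
    sp <- best_split(values[idx], y[idx], min_leaf = min_leaf)
    if (is.na(sp$threshold)) return()
    acc[[length(acc) + 1]] <<- c(threshold = sp$threshold, gain = sp$gain)
    left <- idx[values[idx] <= sp$threshold]
    right <- idx[values[idx] > sp$threshold]
    recurse(left, depth + 1)
    recurse(right, depth + 1)
  }
  recurse(seq_along(values), 1)
  thr <- vapply(acc, `[[`, 0, "threshold")
  gains <- vapply(acc, `[[`, 0, "gain")
  if (!is.null(max_thresholds) && length(thr) > max_thresholds) {
    keep <- order(gains, decreasing = TRUE)[seq_len(max_thresholds)]
    thr <- thr[keep]
    gains <- gains[keep]
  }
  ord <- order(thr)
  discretization(thr[ord], gains = gains[ord], variable = variable)
}

discretization <- function(thresholds, gains = NULL, variable = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  k <- length(thresholds)
  labels <- if (k == 0) "(-Inf, Inf)" else {
    c(sprintf("(-Inf, %g]", thresholds[1]),
      if (k > 1) sprintf("(%g, %g]", thresholds[-k], thresholds[-1]),
      sprintf("(%g, Inf)", thresholds[k]))
  }
  structure(list(variable = variable, thresholds = as.numeric(thresholds),
                 gains = gains, labels = labels),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("Discretization of %s: %s\n",
              if (is.null(x$variable)) "<variable>" else x$variable,
              paste(x$labels, collapse = " | ")))
  invisible(x)
}

#' Bin a value against a set of thresholds
#'
#' Intervals are left-open, right-closed: `(-Inf, t1], (t1, t2], ...,
#' (tk, Inf)`, so printed "<= t" category boundaries are honored (a value
#' equal to a threshold falls in the lower category).  The category index
#' is 0-based.
#'
#' @param value Numeric vector.
#' @param disc A `discretization` object, or a numeric vector of sorted
#'   thresholds.
#' @return Integer vector of 0-based category indices.
#' @export
bin_variable <- function(value, disc) {
  thresholds <- if (inherits(disc, "discretization")) disc$thresholds
                else as.numeric(disc)
  if (!length(thresholds)) return(rep(0L, length(value)))
  as.integer(rowSums(outer(value, thresholds, `>`)))
}
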