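# Stage-1 factor screening: prevalence filter, symptom--severity
# correlation, and good-vs-poor univariate comparisons.

screen_result <- function(factor, test, statistic, p_value, alpha = 0.05) {
  data.frame(factor = factor, test = test, statistic = statistic,
             p_value = p_value, selected = p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Keep symptoms with a day-1 appearance rate at or above a threshold
#'
#' Rare findings are removed before any testing; the default threshold is a
#' 5\% day-1 prevalence (boundary inclusive), computed before change-status
#' analysis.
#'
#' @param cohort A [cohort_table()].
#' @param threshold Minimum day-1 appearance proportion (default 0.05).
#' @return Character vector of retained symptom names, panel order
#'   preserved.
#' @export
prevalence_filter <- function(cohort, threshold = 0.05) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  panel <- cohort_panel(cohort)
  rate <- vapply(panel, function(s) mean(cohort[[paste0("sym_", s, "_d1")]]),
                 0)
  panel[rate >= threshold]
}

#' Rank (or product-moment) correlation with large-sample p-value
#'
#' Spearman correlation on midranks by default; the p-value comes from the
#' t approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r` and `p`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Chi-square comparison of a binary factor between outcome groups
#'
#' Pearson chi-square on the 2x2 table, without continuity correction,
#' 1 degree of freedom.
#'
#' @param good_yes,good_total Factor-present count and group size among good
#'   recoveries.
#' @param poor_yes,poor_total Same among poor recoveries.
#' @param factor Factor name carried into the result.
#' @param alpha Significance level for the `selected` flag.
#' @return One-row data frame: `factor, test, statistic, p_value, selected`.
#' @export
compare_categorical <- function(good_yes, good_total, poor_yes, poor_total,
                                factor = "factor", alpha = 0.05) {
  if (good_total <= 0 || poor_total <= 0 ||
      good_yes > good_total || poor_yes > poor_total ||
      good_yes < 0 || poor_yes < 0) {
    stop("counts must satisfy 0 <= yes <= total, total > 0", call. = FALSE)
  }
  tab <- rbind(good = c(yes = good_yes, no = good_total - good_yes),
               poor = c(yes = poor_yes, no = poor_total - poor_yes))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("chi-square undefined: an expected cell is 0", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  screen_result(factor, "chi_square", unname(ct$statistic),
                unname(ct$p.value), alpha)
}

#' Compare a continuous factor between outcome groups
#'
#' Either the pooled-variance independent-samples t-test or the
#' Mann-Whitney U test (continuity-corrected normal approximation with tie
#' correction); the caller chooses the method, defaulting to Mann-Whitney.
#'
#' @param values_good,values_poor Numeric vectors (each of length >= 2).
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @inheritParams compare_categorical
#' @return One-row data frame as in [compare_categorical()]; for
#'   Mann-Whitney the statistic is U (number of good-poor pairs with the
#'   good value larger, ties counted half).
#' @export
compare_continuous <- function(values_good, values_poor,
                               method = c("mann_whitney", "t_test"),
                               factor = "factor", alpha = 0.05) {
  method <- match.arg(method)
  if (length(values_good) < 2 || length(values_poor) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (method == "t_test") {
    tt <- stats::t.test(values_good, values_poor, var.equal = TRUE)
    screen_result(factor, "t_test", unname(tt$statistic),
                  unname(tt$p.value), alpha)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(values_good, values_poor,
                         exact = FALSE, correct = TRUE))
    screen_result(factor, "mann_whitney", unname(wt$statistic),
                  unname(wt$p.value), alpha)
  }
}

#' Chi-square on a change-status-by-outcome table
#'
#' Takes the 3x2 table of change status (appear/keep/disappear) against
#' outcome (good/poor), drops all-zero rows, and runs the Pearson chi-square
#' with `(rows - 1)` degrees of freedom.
#'
#' @param counts 3x2 (or r x 2) matrix of counts, columns good/poor.
#' @inheritParams compare_categorical
#' @return One-row data frame as in [compare_categorical()].
#' @export
compare_change_status <- function(counts, factor = "factor", alpha = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 || any(counts < 0)) {
    stop("counts must be an r x 2 nonnegative matrix", call. = FALSE)
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) < 2) {
    stop("change-status test needs at least 2 nonzero rows", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  screen_result(factor, "chi_square", unname(ct$statistic),
                unname(ct$p.value), alpha)
}

#' Screen all candidate prognostic factors of a cohort
#'
#' Runs the full stage-1 screen: the day-1 prevalence filter on the symptom
#' panel, then for every factor the test its type calls for -- chi-square
#' for binary factors (sex, history flags, day-1 symptom presence),
#' the declared continuous-method for age, onset-to-admission time, day-1
#' NIHSS and the NIHSS change, and the change-status chi-square for the
#' day-1-to-day-3 change of each retained symptom.  Symptoms whose change
#' table degenerates to a single nonzero row (no patient changed) are
#' omitted from the change results.
#'
#' @param cohort A [cohort_table()] with `bi_d90` recorded.
#' @param alpha Significance level; `selected` flags `p < alpha`.
#' @param prevalence_threshold Passed to [prevalence_filter()].
#' @param continuous_method `"mann_whitney"` (default) or `"t_test"`.
#' @return Data frame of screen results, one row per tested factor.
#' @export
screen_candidates <- function(cohort, alpha = 0.05,
                              prevalence_threshold = 0.05,
                              continuous_method = c("mann_whitney", "t_test")) {
  continuous_method <- match.arg(continuous_method)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  outcome <- derive_outcome(cohort$bi_d90)
  good <- outcome == "good"
  results <- list()

  for (v in c("age", "onset_hours", "nihss_d1")) {
    results[[v]] <- compare_continuous(cohort[[v]][good], cohort[[v]][!good],
                                       method = continuous_method,
                                       factor = v, alpha = alpha)
  }
  delta <- derive_delta_nihss(cohort$nihss_d1, cohort$nihss_d3)
  results[["delta_nihss"]] <- compare_continuous(
    delta[good], delta[!good], method = continuous_method,
    factor = "delta_nihss", alpha = alpha)

  binary_cols <- c(sex = "sex", stats::setNames(paste0("hx_", HISTORY_FLAGS),
                                                paste0("hx_", HISTORY_FLAGS)))
  for (nm in names(binary_cols)) {
    x <- if (nm == "sex") cohort$sex == "male" else cohort[[nm]] == 1
    results[[nm]] <- compare_categorical(
      sum(x[good]), sum(good), sum(x[!good]), sum(!good),
      factor = nm, alpha = alpha)
  }

  kept <- prevalence_filter(cohort, prevalence_threshold)
  for (s in kept) {
    d1 <- cohort[[paste0("sym_", s, "_d1")]]
    results[[paste0(s, "_day1")]] <- compare_categorical(
      sum(d1[good]), sum(good), sum(d1[!good]), sum(!good),
      factor = paste0(s, "_day1"), alpha = alpha)
    status <- derive_change_status(d1, cohort[[paste0("sym_", s, "_d3")]])
    counts <- vapply(CHANGE_LEVELS, function(lv) {
      c(sum(status == lv & good), sum(status == lv & !good))
    }, numeric(2))
    counts <- t(counts)  # rows disappear/keep/appear, cols good/poor
    if (sum(rowSums(counts) > 0) >= 2) {
      results[[paste0(s, "_change")]] <- compare_change_status(
        counts, factor = paste0(s, "_change"), alpha = alpha)
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}
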