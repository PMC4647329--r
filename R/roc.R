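# ROC construction over scale scores, Youden-index cutoff selection, and
# the validation metrics in the good/poor confusion-count convention.

#' Confusion counts of score-based predictions
#'
#' Applies the strict rule `score > cutoff` predicts poor and tallies the
#' four cells in the good/poor labelling: TG (actual good, predicted good),
#' FP (actual good, predicted poor), TP (actual poor, predicted poor), FG
#' (actual poor, predicted good).
#'
#' @param scores Numeric vector of total scale scores.
#' @param outcomes Character vector of `"good"`/`"poor"` actual outcomes.
#' @param cutoff Decision threshold.
#' @return Object of class `confusion_matrix`: list with counts `tg`,
#'   `fp`, `fg`, `tp`.
#' @export
confusion <- function(scores, outcomes, cutoff) {
  if (!length(scores) || length(scores) != length(outcomes)) {
    stop("scores and outcomes must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (!all(outcomes %in% c("good", "poor"))) {
    stop("outcomes must be 'good' or 'poor'", call. = FALSE)
  }
  pred <- classify_score(scores, cutoff)
  confusion_matrix(tg = sum(outcomes == "good" & pred == "good"),
                   fp = sum(outcomes == "good" & pred == "poor"),
                   fg = sum(outcomes == "poor" & pred == "good"),
                   tp = sum(outcomes == "poor" & pred == "poor"))
}

#' Construct a confusion matrix from its four counts
#'
#' @param tg,fp,fg,tp Nonnegative counts: true good, false poor (actual
#'   good predicted poor), false good (actual poor predicted good), true
#'   poor.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tg, fp, fg, tp) {
  counts <- c(tg = tg, fp = fp, fg = fg, tp = tp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("           predicted good  predicted poor\n"))
  cat(sprintf("actual good %13d %15d\n", x$tg, x$fp))
  cat(sprintf("actual poor %13d %15d\n", x$fg, x$tp))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Uses the good-recovery detection convention: sensitivity is the fraction
#' of actual good recoveries predicted good, `TG / (TG + FP)`; specificity
#' is the fraction of actual poor recoveries predicted poor,
#' `TP / (TP + FG)`; accuracy is `(TG + TP) / (TG + FP + FG + TP)`.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tg + cm$fp == 0) {
    stop("sensitivity undefined: no actual good recoveries (TG + FP = 0)",
         call. = FALSE)
  }
  if (cm$tp + cm$fg == 0) {
    stop("specificity undefined: no actual poor recoveries (TP + FG = 0)",
         call. = FALSE)
  }
  list(sensitivity = cm$tg / (cm$tg + cm$fp),
       specificity = cm$tp / (cm$tp + cm$fg),
       accuracy = (cm$tg + cm$tp) / (cm$tg + cm$fp + cm$fg + cm$tp))
}

#' ROC table over all achievable score cutoffs
#'
#' Candidate cutoffs are the sorted distinct observed scores plus one
#' sentinel below the minimum (under which every patient is predicted
#' poor).  For each cutoff the good-detection sensitivity, poor-detection
#' specificity and Youden index `J = sensitivity + specificity - 1` are
#' tabulated.  With the fixed `score > cutoff => poor` rule, sensitivity is
#' nondecreasing and specificity nonincreasing in the cutoff.
#'
#' @inheritParams confusion
#' @return Data frame of class `roc_curve` with columns `cutoff`, `tg`,
#'   `fp`, `fg`, `tp`, `sens`, `spec`, `youden`.
#' @export
roc_curve <- function(scores, outcomes) {
  if (length(unique(outcomes)) < 2) {
    stop("ROC needs both outcome classes present", call. = FALSE)
  }
  cutoffs <- c(min(scores) - 1, sort(unique(scores)))
  n_good <- sum(outcomes == "good")
  n_poor <- sum(outcomes == "poor")
  good_scores <- scores[outcomes == "good"]
  poor_scores <- scores[outcomes == "poor"]
  tg <- vapply(cutoffs, function(c) sum(good_scores <= c), 0)
  tp <- vapply(cutoffs, function(c) sum(poor_scores > c), 0)
  out <- data.frame(cutoff = cutoffs, tg = tg, fp = n_good - tg,
                    fg = n_poor - tp, tp = tp,
                    sens = tg / n_good, spec = tp / n_poor)
  out$youden <- out$sens + out$spec - 1
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Cutoff maximizing Youden's index
#'
#' Returns the cutoff of a [roc_curve()] with the largest
#' `sensitivity + specificity - 1`; exact ties are broken toward the
#' smallest cutoff.
#'
#' @param curve A [roc_curve()].
#' @return The selected cutoff (numeric scalar).
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  min(curve$cutoff[curve$youden >= max(curve$youden) - 1e-12])
}

#' Trapezoidal area under the ROC curve
#'
#' Convenience summary of discrimination (poor recovery as the positive
#' class); equivalent to the concordance probability with ties counted
#' half.
#'
#' @param curve A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  # TPR for poor = spec, FPR for poor = 1 - sens; order by FPR
  fpr <- rev(1 - curve$sens)
  tpr <- rev(curve$spec)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Validate a scale on a cohort
#'
#' Scores the cohort, tallies the confusion counts at the scale's cutoff
#' and reports the validation metrics together with the full ROC table.
#'
#' @param scale A [scale_definition()].
#' @param cohort A [cohort_table()] with day-90 Barthel Index recorded.
#' @param absent_pair_policy Passed to [score_cohort()].
#' @return List with `confusion`, `metrics`, `roc`, `auc`, `cutoff`.
#' @export
validate_scale <- function(scale, cohort,
                           absent_pair_policy = c("keep", "zero")) {
  absent_pair_policy <- match.arg(absent_pair_policy)
  scored <- score_cohort(scale, cohort,
                         absent_pair_policy = absent_pair_policy)
  outcomes <- derive_outcome(cohort$bi_d90)
  cm <- confusion(scored$total, outcomes, scale$cutoff)
  curve <- roc_curve(scored$total, outcomes)
  list(confusion = cm, metrics = confusion_metrics(cm), roc = curve,
       auc = roc_auc(curve), cutoff = scale$cutoff)
}
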