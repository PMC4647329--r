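# Confusion counts, validation metrics, ROC and Youden cutoff.

test_that("a perfectly separated toy has no misclassifications", {
  scores <- c(1, 2, 3, 12, 13)
  outcomes <- c("good", "good", "good", "poor", "poor")
  cm <- confusion(scores, outcomes, 9.5)
  expect_equal(cm$fp, 0)
  expect_equal(cm$fg, 0)
  m <- confusion_metrics(cm)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))
})

test_that("a score exactly at the cutoff is predicted good", {
  cm <- confusion(c(9.5, 10), c("good", "poor"), 9.5)
  expect_equal(cm$tg, 1)
  expect_equal(cm$tp, 1)
  expect_equal(cm$fp + cm$fg, 0)
})

test_that("confusion matches a one-pass tally oracle on random fixtures", {
  set.seed(53)
  for (i in 1:110) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 16.5, by = 0.5), n, replace = TRUE)
    outcomes <- sample(c("good", "poor"), n, replace = TRUE)
    cutoff <- sample(seq(0.5, 16, by = 0.5), 1)
    cm <- confusion(scores, outcomes, cutoff)
    oracle <- oracle_confusion(scores, outcomes, cutoff)
    expect_equal(unlist(cm[c("tg", "fp", "fg", "tp")]), oracle)
  }
})

test_that("metrics reproduce both published validation rows", {
  # development hospitals: counts (TG, FP, FG, TP) = (159, 73, 30, 151)
  m_dev <- confusion_metrics(confusion_matrix(tg = 159, fp = 73,
                                              fg = 30, tp = 151))
  expect_equal(round(100 * m_dev$sensitivity, 1), 68.5)
  expect_equal(round(100 * m_dev$specificity, 1), 83.4)
  expect_equal(round(100 * m_dev$accuracy, 1), 75.1)
  # external hospital: (32, 14, 5, 25)
  m_ext <- confusion_metrics(confusion_matrix(tg = 32, fp = 14,
                                              fg = 5, tp = 25))
  expect_equal(round(100 * m_ext$sensitivity, 1), 69.6)
  expect_equal(round(100 * m_ext$specificity, 1), 83.3)
  expect_equal(round(100 * m_ext$accuracy, 1), 75.0)
})

test_that("metrics error informatively on an empty class", {
  expect_error(confusion_metrics(confusion_matrix(0, 0, 3, 4)),
               "sensitivity.*TG \\+ FP")
  expect_error(confusion_metrics(confusion_matrix(3, 4, 0, 0)),
               "specificity.*TP \\+ FG")
})

test_that("accuracy equals one minus the misclassification fraction", {
  set.seed(59)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(1:30, 1))
    m <- confusion_metrics(cm)
    n <- cm$tg + cm$fp + cm$fg + cm$tp
    expect_equal(m$accuracy, 1 - (cm$fg + cm$fp) / n)
  }
})

test_that("ROC table matches brute-force recomputation at every threshold", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 16.5, by = 0.5), n, replace = TRUE)
    outcomes <- sample(c("good", "poor"), n, replace = TRUE,
                       prob = c(0.55, 0.45))
    if (length(unique(outcomes)) < 2) next
    curve <- roc_curve(scores, outcomes)
    for (k in sample(nrow(curve), min(5, nrow(curve)))) {
      oracle <- oracle_confusion(scores, outcomes, curve$cutoff[k])
      expect_equal(curve$tg[k], unname(oracle["tg"]))
      expect_equal(curve$sens[k],
                   oracle["tg"] / (oracle["tg"] + oracle["fp"]),
                   ignore_attr = TRUE)
      expect_equal(curve$spec[k],
                   oracle["tp"] / (oracle["tp"] + oracle["fg"]),
                   ignore_attr = TRUE)
    }
    # monotone in the cutoff: good-detection up, poor-detection down
    expect_true(all(diff(curve$sens) >= 0))
    expect_true(all(diff(curve$spec) <= 0))
    expect_true(all(curve$youden >= -1 & curve$youden <= 1))
  }
})

test_that("perfect separation reaches Youden 1; constant scores stay at 0", {
  curve <- roc_curve(c(1, 2, 3, 10, 11),
                     c("good", "good", "good", "poor", "poor"))
  expect_equal(max(curve$youden), 1)
  expect_equal(youden_cutoff(curve), 3)
  flat <- roc_curve(rep(5, 10), rep(c("good", "poor"), 5))
  expect_equal(max(flat$youden), 0)
  expect_equal(youden_cutoff(flat), min(flat$cutoff))  # tie rule
})

test_that("the Youden cutoff is invariant to duplicating observations", {
  set.seed(67)
  scores <- sample(seq(0, 16.5, 0.5), 60, replace = TRUE)
  outcomes <- sample(c("good", "poor"), 60, replace = TRUE)
  c1 <- youden_cutoff(roc_curve(scores, outcomes))
  c2 <- youden_cutoff(roc_curve(rep(scores, 2), rep(outcomes, 2)))
  expect_equal(c1, c2)
})

test_that("AUC is 1 for perfect separation and ~0.5 for random scores", {
  perfect <- roc_curve(c(1, 2, 3, 10, 11),
                       c("good", "good", "good", "poor", "poor"))
  expect_equal(roc_auc(perfect), 1)
  set.seed(71)
  scores <- stats::runif(4000)
  outcomes <- sample(c("good", "poor"), 4000, replace = TRUE)
  expect_lt(abs(roc_auc(roc_curve(scores, outcomes)) - 0.5), 0.05)
  expect_error(roc_curve(1:5, rep("good", 5)), "both outcome classes")
})
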