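# Univariate screening: prevalence filter, correlations, group
# comparisons, and the full screen.

test_that("prevalence filter keeps the 5% boundary inclusive", {
  n <- 100
  base <- generate_cohort(default_params(n = n, seed = 3))
  set_prev <- function(cohort, symptom, k) {
    col <- paste0("sym_", symptom, "_d1")
    cohort[[col]] <- c(rep(1L, k), rep(0L, n - k))
    cohort
  }
  cohort <- set_prev(base, "tinnitus", 5)        # exactly 5%
  cohort <- set_prev(cohort, "irritability", 4)  # 4%
  cohort <- set_prev(cohort, "emaciation", 0)    # never present
  kept <- prevalence_filter(cohort)
  expect_true("tinnitus" %in% kept)
  expect_false("irritability" %in% kept)
  expect_false("emaciation" %in% kept)
  expect_error(prevalence_filter(cohort[0, ]), "empty")
})

test_that("rank correlation handles perfect, inverse and tied data", {
  expect_equal(rank_correlation(1:4, c(10, 20, 30, 40))$r, 1)
  expect_equal(rank_correlation(1:3, 3:1)$r, -1)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(rank_correlation(x, y)$r, oracle_spearman_r(x, y))
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  # antisymmetry: negating y flips the sign of r
  set.seed(1)
  for (i in 1:20) {
    xs <- stats::rnorm(10)
    ys <- stats::rnorm(10)
    expect_equal(rank_correlation(xs, ys)$r,
                 -rank_correlation(xs, -ys)$r, tolerance = 1e-12)
  }
  # self-correlation of any non-constant vector is 1
  set.seed(2)
  for (i in 1:20) {
    xs <- sample(1:5, 12, replace = TRUE)
    if (stats::sd(xs) == 0) next
    expect_equal(rank_correlation(xs, xs)$r, 1)
  }
})

test_that("chi-square on the published anxiety counts is highly significant", {
  res <- compare_categorical(49, 232, 94, 181, factor = "anxiety_day1")
  expect_lt(res$p_value, 0.0005)
  expect_true(res$selected)
})

test_that("identical proportions give statistic 0 and p = 1", {
  res <- compare_categorical(50, 100, 50, 100)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$selected)
})

test_that("chi-square matches the direct cell-sum oracle on 2x2 tables", {
  res <- compare_categorical(10, 40, 20, 40)
  oracle <- oracle_chisq(rbind(c(10, 30), c(20, 20)))
  expect_equal(res$statistic, oracle$statistic)
  expect_equal(res$p_value, oracle$p)
  set.seed(42)
  for (i in 1:120) {
    gt <- sample(10:60, 1); pt <- sample(10:60, 1)
    gy <- sample(1:(gt - 1), 1); py <- sample(1:(pt - 1), 1)
    res <- compare_categorical(gy, gt, py, pt)
    oracle <- oracle_chisq(rbind(c(gy, gt - gy), c(py, pt - py)))
    expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney separates extreme groups and matches t-test contract", {
  good <- 1:20
  poor <- 101:120
  expect_lt(compare_continuous(good, poor)$p_value, 0.001)
  expect_lt(compare_continuous(good, poor, method = "t_test")$p_value, 0.001)
  same <- c(1, 2, 3, 4, 5)
  expect_equal(compare_continuous(same, same)$p_value, 1)
  expect_error(compare_continuous(1, 1:5), "at least 2")
})

test_that("Mann-Whitney U and p agree with exact permutation enumeration", {
  set.seed(7)
  for (i in 1:110) {
    n1 <- sample(6:8, 1)
    n2 <- sample(6:8, 1)
    x <- sample(1:9, n1, replace = TRUE)
    y <- sample(1:9, n2, replace = TRUE)
    if (length(unique(c(x, y))) < 2) next
    res <- compare_continuous(x, y)
    expect_equal(res$statistic, oracle_u_statistic(x, y))
    # corrected normal approximation vs exact permutation p at small n
    expect_lt(abs(res$p_value - oracle_u_exact_p(x, y)), 0.12)
  }
})

test_that("change-status chi-square matches the oracle and the published row", {
  # circumrotating change counts (appear/keep/disappear x good/poor)
  counts <- rbind(c(0, 4), c(220, 174), c(12, 3))
  res <- compare_change_status(counts, factor = "circumrotating_change")
  expect_lt(res$p_value, 0.05)
  oracle <- oracle_chisq(counts)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)

  equal_cols <- rbind(c(5, 5), c(30, 30), c(10, 10))
  expect_equal(compare_change_status(equal_cols)$p_value, 1)

  with_zero_row <- rbind(c(0, 0), c(30, 20), c(10, 25))
  res0 <- compare_change_status(with_zero_row)
  expect_equal(res0$statistic,
               oracle_chisq(with_zero_row[-1, ])$statistic,
               tolerance = 1e-12)
  expect_error(compare_change_status(rbind(c(0, 0), c(5, 8), c(0, 0))),
               "2 nonzero rows")
})

test_that("screen_candidates finds a planted association and only that class", {
  # outcome driven solely by anxiety: large effect, large n
  p <- default_params(n = 3000, seed = 5)
  p$outcome_model$coefficients[] <- 0
  p$outcome_model$coefficients["anxiety_day1"] <- 2.5
  p$outcome_model$intercept <- NULL
  cohort <- generate_cohort(p)
  res <- screen_candidates(cohort)
  expect_true(res$selected[res$factor == "anxiety_day1"])
  # overwhelming majority of the unrelated factors stay unselected
  others <- res$selected[res$factor != "anxiety_day1"]
  expect_lt(mean(others), 0.2)
})

test_that("under a null generator the selection rate approaches alpha", {
  p <- default_params(n = 2000, seed = 99)
  p$outcome_model$coefficients[] <- 0
  p$outcome_model$intercept <- stats::qlogis(p$target_poor_prop)
  n_rep <- 500
  rates <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p$seed <- 100000 + r
    res <- screen_candidates(generate_cohort(p))
    rates[r] <- mean(res$selected)
  }
  se <- stats::sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - 0.05), 2 * se + 1e-12)
})
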