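# Independent brute-force oracles and in-code fixtures shared by the tests.
# Each oracle recomputes a quantity by the most direct method available,
# without calling the implementation path it checks.

# Pearson chi-square by the direct sum over cells.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Mann-Whitney U (pairs with x > y, ties half) and its exact two-sided
# permutation p-value by full enumeration of group assignments.
oracle_u_statistic <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

oracle_u_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  null_center <- n1 * length(y) / 2
  obs_dev <- abs(oracle_u_statistic(x, y) - null_center)
  # enumerate group assignments; U = (midrank sum of group 1) - n1(n1+1)/2
  r <- rank(pooled)
  assignments <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[assignments], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - null_center) >= obs_dev - 1e-9)
}

# Spearman correlation by the explicit midrank product-moment formula.
oracle_spearman_r <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Best Gini split by a naive double loop over every candidate midpoint.
oracle_best_split <- function(values, labels, min_leaf = 1) {
  gini0 <- function(y) if (!length(y)) 0 else 2 * mean(y) * (1 - mean(y))
  v_sorted <- sort(unique(values))
  best <- list(threshold = NA_real_, gain = 0)
  if (length(v_sorted) < 2) return(best)
  parent <- gini0(labels)
  n <- length(values)
  for (k in seq_len(length(v_sorted) - 1)) {
    thr <- (v_sorted[k] + v_sorted[k + 1]) / 2
    left <- labels[values <= thr]
    right <- labels[values > thr]
    if (length(left) < min_leaf || length(right) < min_leaf) next
    gain <- parent - (length(left) * gini0(left) +
                        length(right) * gini0(right)) / n
    if (gain > best$gain + 1e-12) best <- list(threshold = thr, gain = gain)
  }
  best
}

# Confusion counts by an explicit per-observation loop.
oracle_confusion <- function(scores, outcomes, cutoff) {
  tg <- fp <- fg <- tp <- 0
  for (i in seq_along(scores)) {
    pred_poor <- scores[i] > cutoff
    if (outcomes[i] == "good") {
      if (pred_poor) fp <- fp + 1 else tg <- tg + 1
    } else {
      if (pred_poor) tp <- tp + 1 else fg <- fg + 1
    }
  }
  c(tg = tg, fp = fp, fg = fg, tp = tp)
}

# A small hand-built cohort (6 patients, 3-symptom panel) for I/O and
# scoring tests.
make_small_cohort <- function() {
  data <- data.frame(
    id = paste0("P", 1:6),
    age = c(50.0, 60.0, 70.5, 55.0, 80.0, 45.5),
    sex = c("male", "female", "male", "male", "female", "male"),
    hx_hypertension = c(1, 0, 1, 0, 1, 0),
    hx_stroke = c(0, 0, 1, 0, 0, 0),
    hx_chd = c(0, 1, 0, 0, 1, 0),
    hx_dm = c(0, 1, 1, 0, 0, 0),
    hx_af = c(0, 0, 0, 0, 1, 0),
    onset_hours = c(2.0, 10.5, 23.5, 6.0, 12.0, 1.0),
    nihss_d1 = c(2L, 4L, 12L, 1L, 7L, 3L),
    nihss_d3 = c(0L, 2L, 12L, 1L, 9L, 2L),
    bi_d90 = c(100L, 95L, 20L, 90L, 45L, 85L),
    sym_anxiety_d1 = c(0, 1, 1, 0, 1, 0),
    sym_anxiety_d3 = c(0, 1, 1, 0, 0, 0),
    sym_circumrotating_d1 = c(0, 0, 1, 1, 0, 0),
    sym_circumrotating_d3 = c(0, 1, 1, 0, 0, 0),
    sym_tinnitus_d1 = c(0, 0, 0, 1, 0, 1),
    sym_tinnitus_d3 = c(0, 0, 1, 1, 0, 0),
    stringsAsFactors = FALSE)
  cohort_table(data)
}

# A record hitting the highest category of every default-scale item.
worst_case_record <- function() {
  list(age = 70, hx_dm = 1, sym_anxiety_d1 = 1, nihss_d1 = 12L,
       nihss_d3 = 12L, sym_irritability_d1 = 1,
       sym_circumrotating_d1 = 0, sym_circumrotating_d3 = 1,
       sym_tinnitus_d1 = 0, sym_tinnitus_d3 = 1)
}
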