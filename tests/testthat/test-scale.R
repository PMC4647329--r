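# The 8-item scale: structure, scoring, classification, serialization.

test_that("the default scale has the published structure", {
  sc <- default_scale()
  expect_length(sc$items, 8)
  expect_equal(sc$max_total, 16.5)
  expect_equal(sc$cutoff, 9.5)
  weights <- vapply(sc$items, `[[`, 0, "weight")
  expect_equal(weights, c(1, 1, 1, 1, 1.5, 1, 2, 2.5))
  # points are weight * category index throughout
  for (it in sc$items) {
    expect_equal(it$points, it$weight * seq(0, length(it$points) - 1))
  }
})

test_that("a worst-case record scores the maximum 16.5 and is poor", {
  res <- score_patient(default_scale(), worst_case_record())
  expect_equal(res$total, 16.5)
  expect_equal(res$predicted, "poor")
  expect_equal(unname(res$per_item),
               c(1, 1, 1, 2, 1.5, 1, 4, 5))
})

test_that("an all-reference record scores 0 under the zero policy", {
  rec <- list(age = 50, hx_dm = 0, sym_anxiety_d1 = 0, nihss_d1 = 2L,
              nihss_d3 = 0L, sym_irritability_d1 = 0,
              sym_circumrotating_d1 = 0, sym_circumrotating_d3 = 0,
              sym_tinnitus_d1 = 0, sym_tinnitus_d3 = 0)
  res0 <- score_patient(default_scale(), rec, absent_pair_policy = "zero")
  expect_equal(res0$total, 0)
  expect_equal(res0$predicted, "good")
  # the literal keep reading gives the symptom-free floor of 4.5
  res_keep <- score_patient(default_scale(), rec)
  expect_equal(res_keep$total, 4.5)
})

test_that("a mixed record sums its item points by hand", {
  # age 60 (1) + no DM (0) + no anxiety (0) + NIHSS 4 (1) + no
  # irritability (0) + delta -2 (0) + circumrotating disappears (0) +
  # tinnitus absent both days, keep (2.5) = 4.5, good
  rec <- list(age = 60, hx_dm = 0, sym_anxiety_d1 = 0, nihss_d1 = 4L,
              nihss_d3 = 2L, sym_irritability_d1 = 0,
              sym_circumrotating_d1 = 1, sym_circumrotating_d3 = 0,
              sym_tinnitus_d1 = 0, sym_tinnitus_d3 = 0)
  res <- score_patient(default_scale(), rec)
  expect_equal(res$total, 4.5)
  expect_equal(res$predicted, "good")
})

test_that("threshold boundaries follow the printed <= conventions", {
  sc <- default_scale()
  base <- worst_case_record()
  score_at <- function(field, value) {
    rec <- base
    rec[[field]] <- value
    score_patient(sc, rec)$per_item
  }
  expect_equal(unname(score_at("age", 56.44)["age_degree"]), 0)
  expect_equal(unname(score_at("age", 56.45)["age_degree"]), 1)
  # NIHSS 2 -> 0; 3 and 6 -> 1; 7 -> 2 (three-way partition of integers)
  nihss_points <- vapply(c(2L, 3L, 6L, 7L), function(v) {
    rec <- base
    rec$nihss_d1 <- v
    rec$nihss_d3 <- v  # keep delta at 0
    unname(score_patient(sc, rec)$per_item["nihss_day1_degree"])
  }, 0)
  expect_equal(nihss_points, c(0, 1, 1, 2))
})

test_that("classification is strictly greater than the cutoff", {
  expect_equal(classify_score(10.0, 9.5), "poor")
  expect_equal(classify_score(9.5, 9.5), "good")
  expect_equal(classify_score(0, 9.5), "good")
})

test_that("brute-force enumeration confirms range and granularity", {
  sc <- default_scale()
  totals <- enumerate_totals(sc)
  expect_length(totals, 2 * 2 * 2 * 3 * 2 * 2 * 3 * 3)
  expect_equal(max(totals), 16.5)
  expect_equal(min(totals), 0)
  expect_true(all(abs(totals * 2 - round(totals * 2)) < 1e-9))
})

test_that("raising any single item category never lowers the total", {
  sc <- default_scale()
  point_sets <- lapply(sc$items, `[[`, "points")
  idx_grid <- expand.grid(lapply(point_sets, seq_along))
  totals <- mapply(function(pts, idx) pts[idx], point_sets, idx_grid)
  totals <- rowSums(totals)
  for (j in seq_along(point_sets)) {
    can_raise <- idx_grid[[j]] < length(point_sets[[j]])
    raised <- idx_grid[can_raise, ]
    raised[[j]] <- raised[[j]] + 1
    raised_totals <- rowSums(
      mapply(function(pts, idx) pts[idx], point_sets, raised))
    expect_true(all(raised_totals >= totals[can_raise]))
    # a raise can never flip a poor prediction back to good
    expect_false(any(totals[can_raise] > sc$cutoff &
                       raised_totals <= sc$cutoff))
  }
})

test_that("scoring errors name the missing feature's item", {
  rec <- worst_case_record()
  rec$hx_dm <- NULL
  expect_error(score_patient(default_scale(), rec), "history_dm")
})

test_that("scale JSON serialization round trips", {
  sc <- default_scale()
  path <- withr::local_tempfile(fileext = ".json")
  save_scale(sc, path)
  back <- load_scale(path, strict = TRUE)
  expect_equal(back, sc)
})

test_that("the shipped default scale file reproduces default_scale()", {
  path <- system.file("extdata", "default_scale.json",
                      package = "strokescale")
  expect_true(nzchar(path))
  expect_equal(load_scale(path, strict = TRUE), default_scale())
})

test_that("strict loading rejects a 7-item definition", {
  sc <- default_scale()
  sc7 <- scale_definition(sc$items[1:7], cutoff = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_scale(sc7, path)
  expect_error(load_scale(path, strict = TRUE), "8 items")
  expect_length(load_scale(path)$items, 7)
})

test_that("an altered cutoff is honored by classification", {
  sc <- default_scale()
  custom <- scale_definition(sc$items, cutoff = 8.0, strict = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  save_scale(custom, path)
  loaded <- load_scale(path, strict = TRUE)
  expect_equal(loaded$cutoff, 8.0)
  rec <- worst_case_record()
  rec$sym_tinnitus_d3 <- 0  # drop 5 -> total 11.5... still poor at 8.0
  rec$sym_circumrotating_d3 <- 0
  # total = 16.5 - 5(tinnitus appear->keep is 2.5 less)...
  res <- score_patient(loaded, rec)
  expect_equal(res$predicted, classify_score(res$total, 8.0))
})

test_that("non-half-point or malformed definitions are rejected", {
  expect_error(scale_item("x", 1, "binary", "hx_dm", points = c(0, 0.3)),
               "multiples of 0.5")
  expect_error(scale_item("x", 1, "threshold", "age", points = c(0, 1),
                          thresholds = c(5, 5)), "strictly increasing")
  expect_error(scale_definition(list(), cutoff = 1), "nonempty")
  sc <- default_scale()
  expect_error(scale_definition(sc$items, cutoff = 17), "cutoff")
})
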