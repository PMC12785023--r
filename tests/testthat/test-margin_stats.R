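grid_map <- function(vals, k, nrow = 1) label_map(matrix(vals, nrow = nrow), k)

square_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE; m
}

# 1 x 8 grid: tumor ROIs over columns 1:2 and 3:4, peritumor over 5:6, 7:8
toy_rois <- function() {
  roi_set(list(square_mask(1, 8, 1, 1:2), square_mask(1, 8, 1, 3:4),
               square_mask(1, 8, 1, 5:6), square_mask(1, 8, 1, 7:8)),
          c("tumor", "tumor", "peritumor", "peritumor"))
}

test_that("tumor reference label is the modal ROI label with low tie-break", {
  map <- grid_map(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), 2)
  expect_equal(tumor_reference_label(map, toy_rois()), 0L)
  map2 <- grid_map(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L), 2)
  expect_equal(tumor_reference_label(map2, toy_rois()), 0L)  # tie -> smaller
  map3 <- grid_map(c(NA, NA, NA, NA, 0L, 0L, 1L, 1L), 2)
  expect_error(tumor_reference_label(map3, toy_rois()), "no tissue")
})

test_that("match percentage counts peritumor pixels with the tumor label", {
  map <- grid_map(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L), 2)
  # 4 peritumor pixels, 1 carries label 0 -> 25%
  expect_equal(peritumor_match_pct(map, toy_rois(), 0L), 25)
  ma <- margin_assessment(map, toy_rois(), threshold = 30)
  expect_true(ma$recognized)
  # strict inequality: exactly at threshold is NOT recognized
  expect_false(margin_assessment(map, toy_rois(), threshold = 25)$recognized)
  expect_false(margin_assessment(map, toy_rois(), threshold = 0)$recognized)
})

test_that("NO_TISSUE pixels are excluded from both match counts", {
  map <- grid_map(c(0L, 0L, 0L, 0L, NA, 1L, 1L, 0L), 2)
  # 3 valid peritumor pixels, 1 matching
  expect_equal(peritumor_match_pct(map, toy_rois(), 0L), 100 / 3)
})

test_that("raising the threshold never unrecognizes a margin", {
  set.seed(42)
  for (r in 1:20) {
    pct <- stats::runif(1, 0, 100)
    t1 <- stats::runif(1, 0, 100); t2 <- t1 + stats::runif(1, 0, 50)
    if (pct < t1) expect_true(pct < t2)
  }
})

test_that("exact binomial tail reproduces the closed form", {
  expect_equal(recognition_binomial_test(9, 10)$p_value, 11 / 1024,
               tolerance = 1e-15)
  expect_equal(round(recognition_binomial_test(9, 10)$p_value, 3), 0.011)
  expect_equal(recognition_binomial_test(10, 10)$p_value, 1 / 1024,
               tolerance = 1e-15)
  expect_equal(recognition_binomial_test(5, 10)$p_value, 638 / 1024,
               tolerance = 1e-15)
  # exhaustive agreement with sum_{i>=s} C(n,i)/2^n and with binom.test
  for (n in 1:12) for (s in 0:n) {
    closed <- sum(choose(n, s:n)) / 2^n
    p <- recognition_binomial_test(s, n)$p_value
    expect_equal(p, closed, tolerance = 1e-12)
    if (s > 0)
      expect_equal(p, stats::binom.test(s, n, 0.5,
                                        alternative = "greater")$p.value,
                   tolerance = 1e-12)
  }
})

test_that("information content separates constant from structured maps", {
  const_map <- label_map(matrix(0L, 60, 60), 1)
  checker <- label_map(outer(1:60, 1:60, function(i, j) (i + j) %% 2), 2)
  expect_lt(info_content(const_map)$bytes, info_content(checker)$bytes)
  expect_identical(info_content(checker)$bytes, info_content(checker)$bytes)
  expect_equal(info_content(checker)$kb, info_content(checker)$bytes / 1024)
})

test_that("trend test recovers an exact slope on collinear input", {
  rec <- data.frame(mode = "positive", window_index = 1:4,
                    kb = c(100, 80, 60, 40))
  tt <- trend_tests(rec)
  expect_equal(tt$per_mode$slope, -20)
  expect_lt(tt$per_mode$p_decreasing, 1e-12)
  flat <- data.frame(mode = "positive", window_index = 1:4, kb = rep(5, 4))
  expect_equal(trend_tests(flat)$per_mode$slope, 0)
  expect_equal(trend_tests(flat)$per_mode$p_decreasing, 1)
  expect_error(trend_tests(data.frame(mode = "positive", window_index = 1,
                                      kb = 1)), "two mass windows")
})

test_that("slope-difference test has power at the designed effect size", {
  set.seed(314)
  hits <- 0L
  for (rep in 1:100) {
    idx <- rep(1:4, times = 10)
    rec <- rbind(
      data.frame(mode = "positive", window_index = idx,
                 kb = 100 - 20 * idx + stats::rnorm(40, 0, 2)),
      data.frame(mode = "negative", window_index = idx,
                 kb = 100 + stats::rnorm(40, 0, 2)))
    if (trend_tests(rec)$slope_difference$p_value < 0.005) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("per-case assessment has the factorial shape and honors thresholds", {
  ph <- make_phantom(default_phantom_spec(seed = 2, mode = "negative",
                                          width = 24, height = 24))
  res <- assess_case(list(negative = ph$cube), ph$truth$rois)
  expect_equal(nrow(res), 4 * 2)   # 4 windows x k in {2, 10}
  expect_true(all(res$match_pct >= 0 & res$match_pct <= 100))
  expect_true(all(res$advisory_only == (res$k != 2)))
  expect_true(all(res$heterogeneity[res$k == 10] >=
                    res$heterogeneity[res$k == 2]))
  res0 <- assess_case(list(negative = ph$cube), ph$truth$rois, threshold = 0)
  expect_false(any(res0$recognized))
})
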