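test_that("the stone-location proportions reproduce the published p-values", {
  distal <- two_proportion_z_test(51, 100, 5, 20)
  expect_equal(round_half_up(distal$p_value, 3), 0.033)
  mid <- two_proportion_z_test(16, 100, 7, 20)
  expect_equal(round_half_up(mid$p_value, 3), 0.049)
})

test_that("equal proportions give z = 0 and p = 1", {
  r <- two_proportion_z_test(10, 100, 2, 20)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("degenerate pooled proportions are flagged with p = 1", {
  r0 <- two_proportion_z_test(0, 100, 0, 20)
  expect_equal(r0$p_value, 1)
  expect_identical(r0$note, "degenerate_variance")
  r1 <- two_proportion_z_test(100, 100, 20, 20)
  expect_identical(r1$note, "degenerate_variance")
})

test_that("invalid counts are rejected", {
  expect_error(two_proportion_z_test(5, 4, 1, 20), "exceed")
  expect_error(two_proportion_z_test(-1, 10, 1, 20), "non-negative")
  expect_error(two_proportion_z_test(0, 0, 1, 20), "n >= 1")
})

test_that("the z-test matches the uncorrected chi-square oracle on random inputs", {
  withr::local_seed(2024)
  for (i in 1:1000) {
    n1 <- sample(2:200, 1); n2 <- sample(2:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    mine <- two_proportion_z_test(x1, n1, x2, n2)
    pooled <- (x1 + x2) / (n1 + n2)
    if (pooled %in% c(0, 1)) next
    oracle <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
    )
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    # and against a direct normal-CDF recomputation
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    expect_equal(mine$p_value, 2 * pnorm(-abs((x1 / n1 - x2 / n2) / se)),
                 tolerance = 1e-12)
  }
})

test_that("swapping arms preserves the two-sided p and negates the statistic", {
  withr::local_seed(99)
  for (i in 1:50) {
    n1 <- sample(5:100, 1); n2 <- sample(5:100, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    a <- two_proportion_z_test(x1, n1, x2, n2)
    b <- two_proportion_z_test(x2, n2, x1, n1)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$statistic, -b$statistic)
  }
  a <- summary_t_test(10, 2, 30, 11, 3, 40)
  b <- summary_t_test(11, 3, 40, 10, 2, 30)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, -b$statistic)
})

test_that("scaling both arms fourfold sharpens an existing difference", {
  base <- two_proportion_z_test(51, 100, 5, 20)
  big <- two_proportion_z_test(204, 400, 20, 80)
  expect_lt(big$p_value, base$p_value)
})

test_that("summary t-tests reproduce the published continuous comparisons", {
  age <- summary_t_test(55.66, 17.7, 100, 66.73, 14.8, 20)
  expect_equal(age$statistic, -2.617, tolerance = 5e-4)
  expect_equal(age$df, 118)
  expect_equal(round_half_up(age$p_value, 3), 0.010)
  size <- summary_t_test(8.24, 4.46, 100, 10.12, 4.72, 20)
  expect_equal(size$p_value, 0.0909, tolerance = 5e-3)
  welch <- summary_t_test(55.66, 17.7, 100, 66.73, 14.8, 20, variant = "welch")
  expect_lt(welch$df, 118)
})

test_that("summary t-test against t.test on exactly moment-matched samples", {
  # construct raw vectors with exact mean/sd, then compare with stats::t.test
  make <- function(m, s, n) {
    x <- seq_len(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  x1 <- make(55.66, 17.7, 100); x2 <- make(66.73, 14.8, 20)
  mine <- summary_t_test(55.66, 17.7, 100, 66.73, 14.8, 20)
  oracle <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-10)
  mine_w <- summary_t_test(55.66, 17.7, 100, 66.73, 14.8, 20, variant = "welch")
  oracle_w <- stats::t.test(x1, x2)
  expect_equal(mine_w$p_value, oracle_w$p.value, tolerance = 1e-10)
  expect_equal(mine_w$df, unname(oracle_w$parameter), tolerance = 1e-8)
})

test_that("degenerate variances in the t-test are flagged", {
  same <- summary_t_test(5, 0, 10, 5, 0, 10)
  expect_equal(same$p_value, 1)
  diff <- summary_t_test(5, 0, 10, 6, 0, 10)
  expect_equal(diff$p_value, 0)
  expect_identical(diff$note, "degenerate_variance")
})

test_that("identical summaries give p = 1", {
  r <- summary_t_test(10, 3, 50, 10, 3, 50)
  expect_equal(r$p_value, 1)
})

test_that("the comparison table reproduces the published columns", {
  tbl <- cohort_comparison_table(stone_comparisons())
  expect_identical(nrow(tbl), 11L)
  p3 <- function(lbl) tbl$p_value_3dp[tbl$label == lbl]
  expect_equal(p3("share_distal_ureteric_stones"), 0.033)
  expect_equal(p3("share_mid_ureteric_stones"), 0.049)
  # all four secondary-outcome p-values within 0.005 of the printed column
  printed <- c(complications = 0.839, complete_clearance = 0.731,
               re_intervention = 0.418, re_admission = 0.834)
  for (lbl in names(printed)) {
    expect_lt(abs(tbl$p_value[tbl$label == lbl] - printed[[lbl]]), 0.005)
  }
})

test_that("an empty comparison table yields an empty result", {
  empty <- stone_comparisons()[0, ]
  out <- cohort_comparison_table(empty)
  expect_identical(nrow(out), 0L)
  expect_true(all(c("label", "p_value", "p_value_3dp") %in% names(out)))
})
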