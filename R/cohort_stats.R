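#' Pooled two-proportion z-test
#'
#' Compares an outcome proportion between two arms using the pooled
#' two-sample z statistic without continuity correction:
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)} and a two-sided p-value from
#' the standard normal. This is the squared-root of the uncorrected
#' chi-square test (`prop.test(correct = FALSE)`), the convention that
#' matches how categorical comparisons are reported for these cohorts.
#'
#' @param successes_1,n_1 Events and arm size for arm 1.
#' @param successes_2,n_2 Events and arm size for arm 2.
#' @param label Optional comparison label carried into the output.
#' @return A one-row tibble: `label`, `estimate_1`, `estimate_2`,
#'   `statistic` (z), `df` (`NA` for a z-test), `p_value`, `method`,
#'   `note` (degenerate-variance flag, else `NA`).
#' @export
#' @examples
#' two_proportion_z_test(51, 100, 5, 20)   # p ~= 0.033
two_proportion_z_test <- function(successes_1, n_1, successes_2, n_2, label = NA_character_) {
  counts <- c(successes_1, n_1, successes_2, n_2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_stonecea("successes and sample sizes must be non-negative integers")
  }
  if (n_1 < 1 || n_2 < 1) abort_stonecea("each arm needs n >= 1")
  if (successes_1 > n_1 || successes_2 > n_2) {
    abort_stonecea("successes cannot exceed the arm size")
  }
  p1 <- successes_1 / n_1
  p2 <- successes_2 / n_2
  pooled <- (successes_1 + successes_2) / (n_1 + n_2)
  note <- NA_character_
  if (pooled %in% c(0, 1)) {
    z <- 0
    p <- 1
    note <- "degenerate_variance"
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n_1 + 1 / n_2))
    z <- (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(
    label = label, estimate_1 = p1, estimate_2 = p2,
    statistic = z, df = NA_real_, p_value = p,
    method = "two-proportion z (pooled, no continuity correction)",
    note = note
  )
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided two-sample t-test from per-arm mean, SD and n —
#' the form needed when only a published summary table is available.
#' `variant = "pooled"` uses the classical equal-variance statistic with
#' `df = n1 + n2 - 2`; `variant = "welch"` uses the Welch–Satterthwaite
#' approximation.
#'
#' @param mean_1,sd_1,n_1 Summary statistics for arm 1 (`n_1 >= 2`).
#' @param mean_2,sd_2,n_2 Summary statistics for arm 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param label Optional comparison label.
#' @return A one-row tibble: `label`, `estimate_1`, `estimate_2`,
#'   `statistic` (t), `df`, `p_value`, `method`, `note`.
#' @export
#' @examples
#' summary_t_test(55.66, 17.7, 100, 66.73, 14.8, 20)  # p ~= 0.010
summary_t_test <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2,
                           variant = c("pooled", "welch"), label = NA_character_) {
  variant <- match.arg(variant)
  if (sd_1 < 0 || sd_2 < 0) abort_stonecea("standard deviations must be non-negative")
  if (n_1 < 2 || n_2 < 2) abort_stonecea("each arm needs n >= 2")
  note <- NA_character_
  if (sd_1 == 0 && sd_2 == 0) {
    note <- "degenerate_variance"
    if (mean_1 == mean_2) {
      t <- 0; df <- n_1 + n_2 - 2; p <- 1
    } else {
      t <- sign(mean_1 - mean_2) * Inf; df <- n_1 + n_2 - 2; p <- 0
    }
  } else if (variant == "pooled") {
    sp2 <- ((n_1 - 1) * sd_1^2 + (n_2 - 1) * sd_2^2) / (n_1 + n_2 - 2)
    se <- sqrt(sp2 * (1 / n_1 + 1 / n_2))
    t <- (mean_1 - mean_2) / se
    df <- n_1 + n_2 - 2
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    v1 <- sd_1^2 / n_1
    v2 <- sd_2^2 / n_2
    se <- sqrt(v1 + v2)
    t <- (mean_1 - mean_2) / se
    df <- (v1 + v2)^2 / (v1^2 / (n_1 - 1) + v2^2 / (n_2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(
    label = label, estimate_1 = mean_1, estimate_2 = mean_2,
    statistic = t, df = df, p_value = p,
    method = paste0("two-sample t (", variant, ", from summary statistics)"),
    note = note
  )
}

#' Between-arm comparison table
#'
#' Runs the appropriate test for each row of a comparison table: rows with
#' `type = "proportion"` get [two_proportion_z_test()] on
#' `x1, n1, x2, n2`; rows with `type = "continuous"` get
#' [summary_t_test()] on `mean1, sd1, n1, mean2, sd2, n2`.
#'
#' @param comparisons A data frame with columns `label`, `type`, and the
#'   columns required by each row's test (unused cells may be `NA`).
#' @param variant t-test variant for continuous rows.
#' @return A tibble with one row per comparison: the input label and arm
#'   summaries, `statistic`, `df`, `p_value` (exact), and `p_value_3dp`
#'   (rounded half-up to 3 decimals, the table-reporting convention).
#'   Empty input gives an empty tibble.
#' @export
cohort_comparison_table <- function(comparisons, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (nrow(comparisons) == 0) {
    return(tibble::tibble(
      label = character(0), type = character(0),
      estimate_1 = numeric(0), estimate_2 = numeric(0),
      statistic = numeric(0), df = numeric(0),
      p_value = numeric(0), p_value_3dp = numeric(0), method = character(0)
    ))
  }
  res <- purrr::pmap(comparisons, function(label, type, ...) {
    row <- list(...)
    if (type == "proportion") {
      out <- two_proportion_z_test(row$x1, row$n1, row$x2, row$n2, label = label)
    } else if (type == "continuous") {
      out <- summary_t_test(row$mean1, row$sd1, row$n1, row$mean2, row$sd2, row$n2,
                            variant = variant, label = label)
    } else {
      abort_stonecea(paste0("unknown comparison type '", type, "' for row '", label, "'"))
    }
    out$type <- type
    out
  })
  res <- dplyr::bind_rows(res)
  res$p_value_3dp <- round_half_up(res$p_value, 3)
  dplyr::select(res, "label", "type", "estimate_1", "estimate_2",
                "statistic", "df", "p_value", "p_value_3dp", "method", "note")
}
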