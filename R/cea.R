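#' Incremental cost-effectiveness ratio
#'
#' Compares a reference strategy against a comparator on cost (GBP) and
#' effect measured as mean inpatient days per patient (lower is better).
#' `delta_cost = cost_cmp - cost_ref` and `delta_effect = effect_cmp -
#' effect_ref` are the incremental cost and the inpatient days averted by
#' the reference; their ratio is the ICER in GBP per inpatient-day averted.
#' The reference dominates when it is strictly cheaper with no worse
#' effect (and vice versa); the ICER is still reported under dominance,
#' matching how such tables are usually printed.
#'
#' @param cost_ref,cost_cmp Expected cost per patient (GBP), non-negative.
#' @param effect_ref,effect_cmp Mean inpatient days per patient.
#' @param reference,comparator Strategy names for the output.
#' @return A one-row tibble of class `cea_result`: `reference`,
#'   `comparator`, `cost_ref`, `cost_cmp`, `effect_ref`, `effect_cmp`,
#'   `delta_cost`, `delta_effect`, `icer` (`NA` when `delta_effect` is 0),
#'   `dominance` (`"none"`, `"reference_dominates"`,
#'   `"comparator_dominates"`).
#' @export
#' @examples
#' compute_icer(4915, 7783, 3.76, 6.11, reference = "EUL", comparator = "DUL")
compute_icer <- function(cost_ref, cost_cmp, effect_ref, effect_cmp,
                         reference = "reference", comparator = "comparator") {
  vals <- c(cost_ref, cost_cmp, effect_ref, effect_cmp)
  if (!all(vapply(vals, is_number, logical(1)))) {
    abort_stonecea("costs and effects must be single finite numbers")
  }
  if (any(vals < 0)) {
    abort_stonecea("costs and effects must be non-negative")
  }
  delta_cost <- cost_cmp - cost_ref
  delta_effect <- effect_cmp - effect_ref
  icer <- if (delta_effect != 0) delta_cost / delta_effect else NA_real_
  dominance <- if (cost_ref < cost_cmp && effect_ref <= effect_cmp) {
    "reference_dominates"
  } else if (cost_cmp < cost_ref && effect_cmp <= effect_ref) {
    "comparator_dominates"
  } else {
    "none"
  }
  out <- tibble::tibble(
    reference = reference, comparator = comparator,
    cost_ref = cost_ref, cost_cmp = cost_cmp,
    effect_ref = effect_ref, effect_cmp = effect_cmp,
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = icer, dominance = dominance
  )
  class(out) <- c("cea_result", class(out))
  out
}

#' Compare strategies from an evaluation table
#'
#' Data-frame-first wrapper around [compute_icer()]: takes the tibble
#' produced by [evaluate_strategies()] and the two strategy names.
#'
#' @param evaluations A tibble with columns `strategy`, `expected_cost`,
#'   `expected_effect`.
#' @param reference,comparator Strategy names present in `evaluations`.
#' @return A one-row `cea_result` tibble (see [compute_icer()]).
#' @export
compare_strategies <- function(evaluations, reference, comparator) {
  pick <- function(s) {
    i <- match(s, evaluations$strategy)
    if (is.na(i)) abort_stonecea(paste0("strategy '", s, "' not found in evaluations"))
    evaluations[i, ]
  }
  r <- pick(reference); c_ <- pick(comparator)
  compute_icer(r$expected_cost, c_$expected_cost,
               r$expected_effect, c_$expected_effect,
               reference = reference, comparator = comparator)
}

#' @export
#' @importFrom generics tidy
#' @method tidy cea_result
#' @rdname compute_icer
#' @param x A `cea_result`.
#' @param ... Unused.
tidy.cea_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
#' @importFrom generics glance
#' @method glance cea_result
#' @rdname compute_icer
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    icer = x$icer,
    dominance = x$dominance
  )
}

#' Convert GBP amounts to EUR for display
#'
#' Computation throughout the package is in GBP; EUR figures are a display
#' convenience. The default rate (1.1367 EUR/GBP) is a representative rate
#' for the 2019–2020 NHS reference-cost year the unit costs come from.
#'
#' @param amount_gbp Numeric vector of GBP amounts.
#' @param rate EUR per GBP; must be positive.
#' @param round_to If non-`NULL`, round the result half-up to this many
#'   decimal places (`0` reproduces whole-euro report figures).
#' @return Numeric vector of EUR amounts.
#' @export
#' @examples
#' convert_currency(2868, rate = 1.1367, round_to = 0)  # 3260
convert_currency <- function(amount_gbp, rate = 1.1367, round_to = NULL) {
  if (!is_number(rate) || rate <= 0) abort_stonecea("rate must be a positive number")
  out <- amount_gbp * rate
  if (!is.null(round_to)) out <- round_half_up(out, round_to)
  out
}
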