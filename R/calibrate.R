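#' Calibrate free parameters to published per-strategy cost totals
#'
#' Branch probabilities and episode costs that the published tables do not
#' pin down are marked `free = TRUE` in the [parameter_set()]. This routine
#' adjusts each strategy's free parameters, within their bounds, until the
#' rolled-back expected cost matches the strategy's target total. Expected
#' cost is affine in each parameter holding the others fixed, so each free
#' parameter is solved by bisection on its monotone restriction; parameters
#' are cycled until the residual falls below `tol`.
#'
#' @param trees A list of [strategy_tree()] objects (one per strategy).
#' @param params A [parameter_set()]; rows with `free = TRUE` and finite
#'   bounds are eligible for adjustment.
#' @param targets Named numeric vector of target expected costs (GBP),
#'   names matching strategy names. Each targeted strategy must reference
#'   at least one free parameter, and the target must lie within the
#'   attainable range (rollback over the free-parameter box).
#' @param tol Acceptable absolute residual in GBP (default £1).
#' @param max_cycles Maximum passes over a strategy's free parameters.
#' @return The calibrated `parameter_set` (fixed parameters unchanged),
#'   with a `calibration` attribute: a tibble of `strategy`, `target`,
#'   `achieved`, `residual`. [generics::tidy()] returns that tibble;
#'   [generics::glance()] summarises the worst residual.
#' @export
#' @examples
#' ps <- parameter_set(parameter("p", "probability", 0.5, free = TRUE))
#' tr <- strategy_tree("toy",
#'   chance_node("ev",
#'     branch("p", terminal_node("hit", cost = 1000)),
#'     branch("1 - p", terminal_node("miss", cost = 0))
#'   )
#' )
#' cal <- calibrate_free_parameters(list(tr), ps, c(toy = 250))
#' get_parameter(cal, "p")$value  # 0.25
calibrate_free_parameters <- function(trees, params, targets, tol = 1, max_cycles = 100) {
  if (inherits(trees, "strategy_tree")) trees <- list(trees)
  strat_names <- vapply(trees, function(t) t$strategy, character(1))
  unknown <- setdiff(names(targets), strat_names)
  if (length(unknown) > 0) {
    abort_stonecea(paste0("calibration target(s) for unknown strategy: ",
                          paste(unknown, collapse = ", ")))
  }
  env <- list2env(parameter_values(params), parent = baseenv())
  results <- list()

  for (sname in names(targets)) {
    target <- as.numeric(targets[[sname]])
    tree <- trees[[match(sname, strat_names)]]
    croot <- compile_tree(tree$root)
    used <- tree_parameters(tree)
    free_idx <- which(params$free & params$name %in% used)
    if (length(free_idx) == 0) {
      abort_stonecea(paste0("strategy '", sname, "' has no free parameters to calibrate"))
    }
    free_names <- params$name[free_idx]
    lower <- params$lower[free_idx]
    upper <- params$upper[free_idx]

    cost_at <- function(x) {
      for (j in seq_along(free_names)) assign(free_names[j], x[j], envir = env)
      rollback_compiled(croot, env)[1]
    }

    x <- params$value[free_idx]
    ext <- box_extremes(cost_at, lower, upper, x)
    if (target < ext$min - tol || target > ext$max + tol) {
      abort_stonecea(sprintf(
        "target %.2f for strategy '%s' is unattainable; attainable expected-cost range is [%.2f, %.2f]",
        target, sname, ext$min, ext$max
      ), class = "stonecea_unattainable_target")
    }

    resid <- cost_at(x) - target
    cycles <- 0L
    while (abs(resid) > 1e-6 && cycles < max_cycles) {
      cycles <- cycles + 1L
      for (j in seq_along(free_names)) {
        g <- function(t) { xj <- x; xj[j] <- t; cost_at(xj) }
        g_lo <- g(lower[j]); g_hi <- g(upper[j])
        if ((target - g_lo) * (target - g_hi) <= 0 && g_lo != g_hi) {
          a <- lower[j]; b <- upper[j]
          fa <- g_lo - target
          mid <- (a + b) / 2
          for (it in seq_len(80)) {
            mid <- (a + b) / 2
            fm <- g(mid) - target
            if (abs(fm) < 1e-9) break
            if (fa * fm <= 0) b <- mid else { a <- mid; fa <- fm }
            if ((b - a) < 1e-13 * max(1, abs(b))) break
          }
          x[j] <- mid
        } else {
          # target outside this coordinate's reach: move to the nearer endpoint
          x[j] <- if (abs(g_lo - target) < abs(g_hi - target)) lower[j] else upper[j]
        }
        resid <- cost_at(x) - target
        if (abs(resid) <= 1e-6) break
      }
    }
    if (abs(resid) > tol) {
      abort_stonecea(sprintf(
        "calibration for strategy '%s' did not converge: residual %.4f GBP after %d cycles",
        sname, resid, cycles
      ))
    }
    params$value[free_idx] <- x
    # keep env in sync for strategies sharing free parameters
    for (j in seq_along(free_names)) assign(free_names[j], x[j], envir = env)
    results[[sname]] <- tibble::tibble(
      strategy = sname, target = target,
      achieved = target + resid, residual = resid
    )
  }

  validate_parameter_set(params)
  out <- as_parameter_set(params)
  attr(out, "calibration") <- dplyr::bind_rows(results)
  class(out) <- c("calibrated_parameter_set", class(out))
  out
}

#' @export
#' @importFrom generics tidy
#' @method tidy calibrated_parameter_set
#' @rdname calibrate_free_parameters
#' @param x A calibrated parameter set.
#' @param ... Unused.
tidy.calibrated_parameter_set <- function(x, ...) {
  attr(x, "calibration")
}

#' @export
#' @importFrom generics glance
#' @method glance calibrated_parameter_set
#' @rdname calibrate_free_parameters
glance.calibrated_parameter_set <- function(x, ...) {
  cal <- attr(x, "calibration")
  tibble::tibble(
    n_strategies = nrow(cal),
    max_abs_residual = max(abs(cal$residual)),
    n_free = sum(x$free)
  )
}
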