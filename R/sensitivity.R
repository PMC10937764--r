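# Which parameters a deterministic sensitivity analysis varies: cost and
# probability inputs. Durations (mean inpatient days) stay fixed — the
# effect denominator of the ICER is held at its cohort value.
sensitivity_roles <- c("probability", "unit_cost", "daily_cost")

varied_parameter_names <- function(tree, params, vary = "all") {
  used <- tree_parameters(tree)
  eligible <- params$name[params$role %in% sensitivity_roles & params$name %in% used]
  if (identical(vary, "all")) return(eligible)
  if (identical(vary, "probabilities")) {
    return(intersect(eligible, params$name[params$role == "probability"]))
  }
  if (identical(vary, "costs")) {
    return(intersect(eligible, params$name[params$role %in% c("unit_cost", "daily_cost")]))
  }
  unknown <- setdiff(vary, params$name)
  if (length(unknown) > 0) {
    abort_stonecea(paste0("unknown parameter(s) in vary: ", paste(unknown, collapse = ", ")),
      class = "stonecea_unknown_parameter")
  }
  intersect(eligible, vary)
}

# box endpoints for one parameter under a +/- fraction perturbation
perturbed_bounds <- function(params, name, fraction) {
  row <- get_parameter(params, name)
  lo <- row$value * (1 - fraction)
  hi <- row$value * (1 + fraction)
  if (row$role == "probability") {
    lo <- min(max(lo, 0), 1)
    hi <- min(max(hi, 0), 1)
  }
  c(lo, hi)
}

# compiled evaluator for a quantity over a set of varied parameters
make_quantity_fun <- function(trees, params, varied, quantity, reference = NULL,
                              comparator = NULL) {
  env <- list2env(parameter_values(params), parent = baseenv())
  if (quantity == "expected_cost") {
    tree <- if (inherits(trees, "strategy_tree")) trees else trees[[1]]
    croot <- compile_tree(tree$root)
    return(function(x) {
      for (j in seq_along(varied)) assign(varied[j], x[j], envir = env)
      rollback_compiled(croot, env, renormalize = TRUE)[1]
    })
  }
  # icer
  snames <- vapply(trees, function(t) t$strategy, character(1))
  tref <- trees[[match(reference, snames)]]
  tcmp <- trees[[match(comparator, snames)]]
  cref <- compile_tree(tref$root)
  ccmp <- compile_tree(tcmp$root)
  eff <- function(tree, v) if (tree$effect_mode == "scalar_override") tree$scalar_effect else v[2]
  den_sign <- local({
    vr <- rollback_compiled(cref, env, renormalize = TRUE)
    vc <- rollback_compiled(ccmp, env, renormalize = TRUE)
    sign(eff(tcmp, vc) - eff(tref, vr))
  })
  function(x) {
    for (j in seq_along(varied)) assign(varied[j], x[j], envir = env)
    vr <- rollback_compiled(cref, env, renormalize = TRUE)
    vc <- rollback_compiled(ccmp, env, renormalize = TRUE)
    den <- eff(tcmp, vc) - eff(tref, vr)
    if (den == 0 || (den_sign != 0 && sign(den) != den_sign)) return(NA_real_)
    (vc[1] - vr[1]) / den
  }
}

#' One-way sensitivity of a result to a single parameter
#'
#' Re-evaluates the target quantity with one parameter moved to
#' `base * (1 - fraction)` and `base * (1 + fraction)` (probabilities
#' clipped to \[0, 1\]; sibling branch probabilities renormalised). Because
#' expected cost is affine in each parameter, the extremes over the whole
#' interval lie at these endpoints.
#'
#' @param trees A [strategy_tree()] (for `quantity = "expected_cost"`) or a
#'   list of strategy trees (for `quantity = "icer"`).
#' @param params A [parameter_set()].
#' @param parameter Name of the parameter to vary.
#' @param fraction Perturbation fraction in (0, 1); the published analysis
#'   uses 0.10.
#' @param quantity `"expected_cost"` or `"icer"`.
#' @param reference,comparator Strategy names, required for `"icer"`.
#' @return A one-row tibble: `parameter`, `base_result`, `low_result`,
#'   `high_result`, `swing` (`|high - low|`).
#' @seealso [tornado()] to rank all parameters, [joint_range()] for joint
#'   variation.
#' @export
one_way_range <- function(trees, params, parameter, fraction = 0.1,
                          quantity = c("expected_cost", "icer"),
                          reference = NULL, comparator = NULL) {
  quantity <- match.arg(quantity)
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1) {
    abort_stonecea("fraction must lie in (0, 1)")
  }
  row <- get_parameter(params, parameter)  # errors on unknown name
  if (quantity == "icer") {
    tree_list <- if (inherits(trees, "strategy_tree")) list(trees) else trees
    if (length(tree_list) < 2) abort_stonecea("quantity 'icer' needs two strategy trees")
    snames <- vapply(tree_list, function(t) t$strategy, character(1))
    reference <- reference %||% snames[1]
    comparator <- comparator %||% snames[2]
    trees <- tree_list
  }
  f <- make_quantity_fun(trees, params, parameter, quantity, reference, comparator)
  b <- perturbed_bounds(params, parameter, fraction)
  base_result <- f(row$value)
  lo <- f(b[1]); hi <- f(b[2])
  tibble::tibble(
    parameter = parameter,
    base_result = base_result,
    low_result = lo, high_result = hi,
    swing = abs(hi - lo)
  )
}

#' Tornado table: one-way ranges for every varied parameter
#'
#' @inheritParams one_way_range
#' @param parameters Parameters to vary; default every cost and probability
#'   parameter the tree references. May also be `"probabilities"` or
#'   `"costs"` to restrict by role, or a character vector of names.
#' @return A tibble of class `stonecea_tornado` with one row per parameter
#'   (columns as in [one_way_range()]), sorted by descending swing. Plot
#'   with [plot_tornado()] or `autoplot()`.
#' @export
tornado <- function(trees, params, parameters = "all", fraction = 0.1,
                    quantity = c("expected_cost", "icer"),
                    reference = NULL, comparator = NULL) {
  quantity <- match.arg(quantity)
  tree_list <- if (inherits(trees, "strategy_tree")) list(trees) else trees
  if (length(parameters) == 1 && parameters %in% c("all", "probabilities", "costs")) {
    nm <- unique(unlist(lapply(tree_list, varied_parameter_names,
                               params = params, vary = parameters)))
  } else {
    nm <- parameters
  }
  out <- dplyr::bind_rows(lapply(nm, function(p) {
    one_way_range(trees, params, p, fraction, quantity, reference, comparator)
  }))
  out <- dplyr::arrange(out, dplyr::desc(.data$swing))
  class(out) <- c("stonecea_tornado", class(out))
  attr(out, "quantity") <- quantity
  out
}

#' Joint deterministic sensitivity ranges
#'
#' Varies all selected cost and probability parameters jointly over the
#' vertices of the ±`fraction` box and reports the min/max of each
#' strategy's expected cost and of the ICER. Expected cost is multilinear
#' in the parameters, so vertex enumeration is exact; when more than
#' `max_vertex_params` parameters are varied, a deterministic
#' coordinate-wise endpoint descent/ascent with multiple starting patterns
#' is used instead. The ICER is evaluated at candidate points directly
#' (never as independent min/max of numerator and denominator); candidates
#' where the effect difference changes sign are flagged and excluded.
#'
#' @param trees A list of [strategy_tree()] objects.
#' @param params A [parameter_set()].
#' @param fraction Perturbation fraction in (0, 1); default 0.10.
#' @param vary `"all"`, `"probabilities"`, `"costs"`, or a character vector
#'   of parameter names.
#' @param reference,comparator Strategy names for the ICER row; defaults to
#'   the first and second tree. Set `reference = NA` to skip the ICER.
#' @param max_vertex_params Largest number of varied parameters for exact
#'   vertex enumeration (2^k evaluations).
#' @return A tibble of class `stonecea_sensitivity`: `quantity`,
#'   `strategy`, `base`, `low`, `high`, `fraction`, `n_varied`, `method`,
#'   `denominator_sign_change`. Every interval contains its base value.
#' @export
joint_range <- function(trees, params, fraction = 0.1, vary = "all",
                        reference = NULL, comparator = NULL,
                        max_vertex_params = 13) {
  if (inherits(trees, "strategy_tree")) trees <- list(trees)
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1) {
    abort_stonecea("fraction must lie in (0, 1)")
  }
  snames <- vapply(trees, function(t) t$strategy, character(1))
  rows <- list()

  range_for <- function(varied, f, base_x) {
    if (length(varied) == 0) {
      v <- f(numeric(0))
      return(list(min = v, max = v, method = "degenerate", n_infeasible = 0L))
    }
    bnds <- vapply(varied, function(p) perturbed_bounds(params, p, fraction), numeric(2))
    box_extremes(f, lower = bnds[1, ], upper = bnds[2, ], base = base_x,
                 max_vertex = max_vertex_params)
  }

  for (i in seq_along(trees)) {
    varied <- varied_parameter_names(trees[[i]], params, vary)
    f <- make_quantity_fun(trees[[i]], params, varied, "expected_cost")
    base_x <- params$value[match(varied, params$name)]
    ext <- range_for(varied, f, base_x)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "expected_cost", strategy = snames[i],
      base = f(base_x), low = ext$min, high = ext$max,
      fraction = fraction, n_varied = length(varied),
      method = ext$method, denominator_sign_change = FALSE
    )
  }

  want_icer <- length(trees) >= 2 && !isTRUE(is.na(reference))
  if (want_icer) {
    reference <- reference %||% snames[1]
    comparator <- comparator %||% snames[2]
    tr <- trees[c(match(reference, snames), match(comparator, snames))]
    varied <- unique(c(varied_parameter_names(tr[[1]], params, vary),
                       varied_parameter_names(tr[[2]], params, vary)))
    f <- make_quantity_fun(tr, params, varied, "icer", reference, comparator)
    base_x <- params$value[match(varied, params$name)]
    ext <- range_for(varied, f, base_x)
    flagged <- ext$n_infeasible > 0L
    if (flagged) {
      rlang::warn(paste0(
        "effect difference changes sign inside the sensitivity box; ICER range ",
        "reported over the ", "feasible-sign subset (",
        ext$n_infeasible, " candidate points excluded)"
      ))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "icer", strategy = paste(reference, "vs", comparator),
      base = f(base_x), low = ext$min, high = ext$max,
      fraction = fraction, n_varied = length(varied),
      method = ext$method, denominator_sign_change = flagged
    )
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("stonecea_sensitivity", class(out))
  out
}
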