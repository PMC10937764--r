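#' Model parameters
#'
#' A parameter set is a tibble with one row per named model input: branch
#' probabilities, unit costs (GBP), per-diem costs (GBP/day) and durations
#' (days). Parameters marked `free = TRUE` are not pinned by published data
#' and are resolved by [calibrate_free_parameters()] within their bounds.
#'
#' @param name Parameter name (a valid R identifier; referenced by tree
#'   expressions).
#' @param role One of `"probability"`, `"unit_cost"`, `"daily_cost"`,
#'   `"duration_days"`.
#' @param value Base value. Probabilities must lie in \[0, 1\]; costs and
#'   durations must be non-negative.
#' @param free Logical; is this parameter subject to calibration?
#' @param lower,upper Closed bounds. Default \[0, 1\] for probabilities and
#'   \[0, Inf) for the other roles; free parameters need finite bounds.
#' @return A one-row tibble (see [parameter_set()]).
#' @export
#' @examples
#' parameter("p_stent", "probability", 0.5, free = TRUE)
parameter <- function(name, role, value, free = FALSE, lower = NULL, upper = NULL) {
  role <- match.arg(role, c("probability", "unit_cost", "daily_cost", "duration_days"))
  if (role == "probability") {
    lower <- lower %||% 0
    upper <- upper %||% 1
  } else {
    lower <- lower %||% 0
    upper <- upper %||% Inf
  }
  tibble::tibble(
    name = as.character(name), role = role, value = as.numeric(value),
    free = isTRUE(free), lower = as.numeric(lower), upper = as.numeric(upper)
  )
}

#' Build and validate a parameter set
#'
#' @param ... One-row tibbles from [parameter()], or data frames with the
#'   same columns, row-bound together.
#' @return A tibble of class `parameter_set` with columns
#'   `name`, `role`, `value`, `free`, `lower`, `upper`.
#' @seealso [parameter()], [set_parameter()], [parameter_values()]
#' @export
parameter_set <- function(...) {
  ps <- dplyr::bind_rows(...)
  as_parameter_set(ps)
}

#' @rdname parameter_set
#' @param x A data frame with parameter columns.
#' @export
as_parameter_set <- function(x) {
  needed <- c("name", "role", "value", "free", "lower", "upper")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort_stonecea(paste0(
      "parameter set is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)[needed]
  validate_parameter_set(x)
  class(x) <- c("parameter_set", class(tibble::tibble()))
  x
}

validate_parameter_set <- function(ps) {
  if (anyDuplicated(ps$name)) {
    dup <- unique(ps$name[duplicated(ps$name)])
    abort_stonecea(paste0("duplicate parameter name(s): ", paste(dup, collapse = ", ")))
  }
  bad_role <- setdiff(unique(ps$role), c("probability", "unit_cost", "daily_cost", "duration_days"))
  if (length(bad_role) > 0) {
    abort_stonecea(paste0("unknown parameter role(s): ", paste(bad_role, collapse = ", ")))
  }
  pr <- ps$role == "probability"
  if (any(pr & (ps$value < 0 | ps$value > 1))) {
    bad <- ps$name[pr & (ps$value < 0 | ps$value > 1)]
    abort_stonecea(paste0("probability parameter(s) outside [0, 1]: ", paste(bad, collapse = ", ")))
  }
  if (any(pr & (ps$lower < 0 | ps$upper > 1))) {
    bad <- ps$name[pr & (ps$lower < 0 | ps$upper > 1)]
    abort_stonecea(paste0("probability bounds outside [0, 1] for: ", paste(bad, collapse = ", ")))
  }
  if (any(!pr & ps$value < 0)) {
    bad <- ps$name[!pr & ps$value < 0]
    abort_stonecea(paste0("negative cost/duration parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (any(ps$lower > ps$upper)) {
    bad <- ps$name[ps$lower > ps$upper]
    abort_stonecea(paste0("lower bound exceeds upper bound for: ", paste(bad, collapse = ", ")))
  }
  if (any(ps$value < ps$lower | ps$value > ps$upper)) {
    bad <- ps$name[ps$value < ps$lower | ps$value > ps$upper]
    abort_stonecea(paste0("base value outside bounds for: ", paste(bad, collapse = ", ")))
  }
  if (any(ps$free & (!is.finite(ps$lower) | !is.finite(ps$upper)))) {
    bad <- ps$name[ps$free & (!is.finite(ps$lower) | !is.finite(ps$upper))]
    abort_stonecea(paste0("free parameter(s) need finite bounds: ", paste(bad, collapse = ", ")))
  }
  invisible(ps)
}

#' Named list of parameter base values
#'
#' @param params A [parameter_set()].
#' @return Named list mapping parameter name to value, suitable as an
#'   evaluation environment for tree expressions.
#' @export
parameter_values <- function(params) {
  stats::setNames(as.list(params$value), params$name)
}

#' Look up one parameter
#'
#' Unknown names are an error, never a silent default.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @return The one-row tibble for that parameter.
#' @export
get_parameter <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) {
    abort_stonecea(paste0("unknown parameter: ", name), class = "stonecea_unknown_parameter")
  }
  params[i, ]
}

#' Set parameter values by name
#'
#' @param params A [parameter_set()].
#' @param name Character vector of parameter names (must all exist).
#' @param value Numeric vector of replacement values, recycled against `name`.
#' @param clamp If `TRUE`, values are clamped to each parameter's bounds
#'   instead of erroring when outside them.
#' @return The updated `parameter_set`.
#' @export
set_parameter <- function(params, name, value, clamp = FALSE) {
  i <- match(name, params$name)
  if (anyNA(i)) {
    abort_stonecea(paste0("unknown parameter: ", paste(name[is.na(i)], collapse = ", ")),
      class = "stonecea_unknown_parameter")
  }
  value <- rep_len(as.numeric(value), length(i))
  if (clamp) value <- pmin(pmax(value, params$lower[i]), params$upper[i])
  params$value[i] <- value
  validate_parameter_set(params)
  params
}

#' Merge estimated parameters into a model parameter set
#'
#' Values in `fragment` overwrite same-named rows of `params`; new names are
#' appended. Used to inject cohort-estimated probabilities into a model.
#'
#' @param params A [parameter_set()].
#' @param fragment A data frame with the same columns (e.g. from
#'   [estimate_parameters()]).
#' @return The merged `parameter_set`.
#' @export
update_parameters <- function(params, fragment) {
  fragment <- as_parameter_set(fragment)
  shared <- intersect(fragment$name, params$name)
  if (length(shared) > 0) {
    i <- match(shared, params$name)
    j <- match(shared, fragment$name)
    params$value[i] <- pmin(pmax(fragment$value[j], params$lower[i]), params$upper[i])
  }
  extra <- fragment[!fragment$name %in% params$name, ]
  as_parameter_set(dplyr::bind_rows(params, extra))
}

#' Perturb parameters by a multiplicative fraction
#'
#' Implements the deterministic-sensitivity perturbation: each named
#' parameter is moved to `value * (1 + delta)`; probabilities are clipped to
#' \[0, 1\]. Two-branch complements written as `1 - p` follow automatically;
#' nodes with three or more sibling branches are renormalised at evaluation
#' time (see `renormalize` in [rollback()]).
#'
#' @param params A [parameter_set()].
#' @param name Names of parameters to perturb.
#' @param delta Signed fraction, e.g. `+0.10` or `-0.10`.
#' @return The perturbed `parameter_set`.
#' @export
perturb_parameters <- function(params, name, delta) {
  i <- match(name, params$name)
  if (anyNA(i)) {
    abort_stonecea(paste0("unknown parameter: ", paste(name[is.na(i)], collapse = ", ")),
      class = "stonecea_unknown_parameter")
  }
  v <- params$value[i] * (1 + delta)
  pr <- params$role[i] == "probability"
  v[pr] <- pmin(pmax(v[pr], 0), 1)
  params$value[i] <- v
  # perturbation may legitimately leave the calibration bounds; widen them
  params$lower[i] <- pmin(params$lower[i], v)
  params$upper[i] <- pmax(params$upper[i], v)
  params
}
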