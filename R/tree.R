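#' Decision-tree nodes
#'
#' A strategy's clinical episode is modelled as a finite tree of chance and
#' terminal nodes (a decision node may appear only at the root of a
#' comparison). Node cost and effect payloads, and branch probabilities, are
#' expressions over named parameters (see [parameter_set()]), written as
#' character strings, e.g. `"cost_urs + los_days * daily_bed_cost"` or
#' `"1 - p_stent"`. Numeric literals are accepted and stored as expressions.
#'
#' @param label Human-readable node label (used in diagnostics and paths).
#' @param cost Cost payload expression (GBP), incurred on reaching the node.
#'   Default `0`.
#' @param effect Effect payload expression (days). Default `0`.
#' @param ... For [chance_node()] and [decision_node()]: child branches
#'   built with [branch()].
#' @return A `tree_node` list with fields `kind`, `label`, `cost`, `effect`,
#'   `branches`.
#' @name tree_node
#' @examples
#' tr <- chance_node("stent in situ?",
#'   branch("p_stent", terminal_node("stent removal", cost = "cost_removal")),
#'   branch("1 - p_stent", terminal_node("no stent"))
#' )
NULL

as_expr_chr <- function(x, what = "expression") {
  if (is.numeric(x)) return(deparse(x))
  if (is.character(x) && length(x) == 1L) return(x)
  abort_stonecea(paste0(what, " must be a number or a single character string"))
}

#' @rdname tree_node
#' @export
terminal_node <- function(label, cost = 0, effect = 0) {
  structure(
    list(kind = "terminal", label = label,
         cost = as_expr_chr(cost, "cost"), effect = as_expr_chr(effect, "effect"),
         branches = list()),
    class = "tree_node"
  )
}

#' @rdname tree_node
#' @export
chance_node <- function(label, ..., cost = 0, effect = 0) {
  branches <- list(...)
  if (!all(vapply(branches, inherits, logical(1), "tree_branch"))) {
    abort_stonecea("chance_node() branches must be built with branch()")
  }
  structure(
    list(kind = "chance", label = label,
         cost = as_expr_chr(cost, "cost"), effect = as_expr_chr(effect, "effect"),
         branches = branches),
    class = "tree_node"
  )
}

#' @rdname tree_node
#' @export
decision_node <- function(label, ..., cost = 0, effect = 0) {
  branches <- list(...)
  structure(
    list(kind = "decision", label = label,
         cost = as_expr_chr(cost, "cost"), effect = as_expr_chr(effect, "effect"),
         branches = branches),
    class = "tree_node"
  )
}

#' @rdname tree_node
#' @param prob Branch-probability expression (chance-node branches); `NULL`
#'   for decision-node branches.
#' @param node Child `tree_node`.
#' @export
branch <- function(prob, node) {
  if (!inherits(node, "tree_node")) abort_stonecea("branch() child must be a tree_node")
  structure(
    list(prob = if (is.null(prob)) NULL else as_expr_chr(prob, "branch probability"),
         node = node),
    class = "tree_branch"
  )
}

#' Strategy tree
#'
#' Binds a root node to a strategy name and an effect convention. The
#' comparison here measures effect as mean inpatient days per patient;
#' because published effects are cohort means rather than tree-derived, the
#' usual mode is a scalar override.
#'
#' @param strategy Strategy name, e.g. `"EUL"` or `"DUL"`.
#' @param root Root `tree_node`.
#' @param scalar_effect Mean effect in days used verbatim as the strategy's
#'   expected effect (`effect_mode = "scalar_override"`). If `NULL`, effects
#'   accumulate along tree payloads (`"tree_accumulated"`).
#' @return A `strategy_tree` object.
#' @export
strategy_tree <- function(strategy, root, scalar_effect = NULL) {
  if (!inherits(root, "tree_node")) abort_stonecea("root must be a tree_node")
  if (!is.null(scalar_effect)) {
    if (!is_number(scalar_effect) || scalar_effect < 0) {
      abort_stonecea("scalar_effect must be a single non-negative number")
    }
  }
  structure(
    list(strategy = as.character(strategy), root = root,
         effect_mode = if (is.null(scalar_effect)) "tree_accumulated" else "scalar_override",
         scalar_effect = scalar_effect),
    class = "strategy_tree"
  )
}

#' @export
print.strategy_tree <- function(x, ...) {
  cat("<strategy_tree> ", x$strategy, "  (effect: ", x$effect_mode,
      if (x$effect_mode == "scalar_override") paste0(" = ", x$scalar_effect, " days"),
      ")\n", sep = "")
  print_node <- function(n, indent, prob) {
    cat(strrep("  ", indent), "- [", substr(n$kind, 1, 1), "] ", n$label,
        if (!is.null(prob)) paste0("  {p: ", prob, "}"),
        if (n$cost != "0") paste0("  {cost: ", n$cost, "}"), "\n", sep = "")
    for (b in n$branches) print_node(b$node, indent + 1, b$prob)
  }
  print_node(x$root, 0, NULL)
  invisible(x)
}

#' Parameter names referenced by a tree
#'
#' @param tree A `strategy_tree` or `tree_node`.
#' @return Character vector of parameter names appearing in any cost,
#'   effect, or branch-probability expression.
#' @export
tree_parameters <- function(tree) {
  root <- if (inherits(tree, "strategy_tree")) tree$root else tree
  vars <- character(0)
  walk <- function(n) {
    vars <<- c(vars, all.vars(str2lang(n$cost)), all.vars(str2lang(n$effect)))
    for (b in n$branches) {
      if (!is.null(b$prob)) vars <<- c(vars, all.vars(str2lang(b$prob)))
      walk(b$node)
    }
  }
  walk(root)
  unique(vars)
}

# ---- compiled evaluation -----------------------------------------------

# Pre-parse every expression once; joint_range and calibration evaluate the
# same tree thousands of times.
compile_tree <- function(root) {
  comp <- function(n) {
    list(kind = n$kind, label = n$label,
         cost = str2lang(n$cost), cost_chr = n$cost,
         effect = str2lang(n$effect),
         branches = lapply(n$branches, function(b) {
           list(prob = if (is.null(b$prob)) NULL else str2lang(b$prob),
                prob_chr = b$prob, node = comp(b$node))
         }))
  }
  comp(root)
}

eval_expr <- function(lang, env, what, label) {
  val <- tryCatch(eval(lang, envir = env), error = function(e) {
    miss <- regmatches(conditionMessage(e), regexpr("'[^']+'", conditionMessage(e)))
    abort_stonecea(paste0(
      "cannot evaluate ", what, " at node '", label, "': ",
      if (length(miss) > 0) paste0("unknown parameter ", miss) else conditionMessage(e)
    ), class = "stonecea_unknown_parameter")
  })
  if (!is_number(val)) {
    abort_stonecea(paste0(what, " at node '", label, "' is not a finite number"))
  }
  val
}

branch_probs <- function(cn, env, renormalize, tol = 1e-9) {
  p <- vapply(cn$branches, function(b) {
    if (is.null(b$prob)) {
      abort_stonecea(paste0("chance node '", cn$label, "' has a branch without a probability"))
    }
    eval_expr(b$prob, env, "branch probability", cn$label)
  }, numeric(1))
  if (renormalize) {
    p <- pmin(pmax(p, 0), 1)
    s <- sum(p)
    if (s <= 0) abort_stonecea(paste0("chance node '", cn$label, "' has zero total probability"))
    p <- p / s
  } else {
    bad <- which(p < -tol | p > 1 + tol)
    if (length(bad) > 0) {
      abort_stonecea(paste0(
        "branch probability '", cn$branches[[bad[1]]]$prob_chr, "' at node '",
        cn$label, "' is ", format(p[bad[1]]), ", outside [0, 1]"
      ), class = "stonecea_probability_error")
    }
    if (abs(sum(p) - 1) > tol) {
      abort_stonecea(paste0(
        "branch probabilities at node '", cn$label, "' sum to ", format(sum(p)),
        ", expected 1"
      ), class = "stonecea_probability_error")
    }
  }
  p
}

rollback_compiled <- function(cn, env, renormalize = FALSE) {
  cost <- eval_expr(cn$cost, env, "cost payload", cn$label)
  effect <- eval_expr(cn$effect, env, "effect payload", cn$label)
  if (cn$kind == "terminal" || length(cn$branches) == 0) {
    return(c(cost, effect))
  }
  if (cn$kind == "decision") {
    abort_stonecea(paste0("cannot roll back through decision node '", cn$label,
                          "'; evaluate each strategy separately"))
  }
  p <- branch_probs(cn, env, renormalize)
  acc <- c(0, 0)
  for (i in seq_along(cn$branches)) {
    acc <- acc + p[i] * rollback_compiled(cn$branches[[i]]$node, env, renormalize)
  }
  c(cost, effect) + acc
}

# ---- public evaluation --------------------------------------------------

#' Expected-value rollback of a strategy tree
#'
#' Recursive expectation from leaves to root: a terminal contributes its
#' payload; a chance node contributes its payload plus the
#' probability-weighted sum of its children. Expected effect is accumulated
#' the same way, unless the strategy carries a scalar override (mean
#' inpatient days), in which case that scalar is reported.
#'
#' @param tree A [strategy_tree()].
#' @param params A [parameter_set()].
#' @param renormalize If `TRUE`, branch probabilities at each chance node
#'   are clipped to \[0, 1\] and rescaled to sum to 1 before weighting —
#'   the convention used when parameters have been perturbed for
#'   sensitivity analysis. If `FALSE` (default), out-of-range or
#'   non-conserving probabilities are an error naming the offending
#'   expression and node.
#' @return A one-row tibble: `strategy`, `expected_cost`, `expected_effect`.
#' @seealso [enumerate_paths()] for the path-by-path oracle,
#'   [evaluate_strategies()] to evaluate several trees at once.
#' @export
#' @examples
#' tr <- strategy_tree("toy",
#'   chance_node("flip",
#'     branch(0.25, terminal_node("hi", cost = 1000)),
#'     branch(0.75, terminal_node("lo", cost = 0))
#'   )
#' )
#' rollback(tr, parameter_set())
rollback <- function(tree, params, renormalize = FALSE) {
  stopifnot(inherits(tree, "strategy_tree"))
  env <- list2env(parameter_values(params), parent = baseenv())
  v <- rollback_compiled(compile_tree(tree$root), env, renormalize)
  tibble::tibble(
    strategy = tree$strategy,
    expected_cost = v[1],
    expected_effect = if (tree$effect_mode == "scalar_override") tree$scalar_effect else v[2]
  )
}

#' Evaluate several strategies
#'
#' @param trees A list of [strategy_tree()] objects.
#' @inheritParams rollback
#' @return A tibble with one row per strategy (see [rollback()]).
#' @export
evaluate_strategies <- function(trees, params, renormalize = FALSE) {
  if (inherits(trees, "strategy_tree")) trees <- list(trees)
  dplyr::bind_rows(lapply(trees, rollback, params = params, renormalize = renormalize))
}

#' Enumerate root-to-terminal paths
#'
#' The brute-force counterpart of [rollback()]: every root-to-terminal path
#' with its probability and accumulated payloads. Serves as the independent
#' oracle for the rollback recursion — `sum(path_probability * path_cost)`
#' must equal the rolled-back expected cost.
#'
#' @inheritParams rollback
#' @return A tibble: `path_probability`, `path_cost`, `path_effect`,
#'   `node_labels` (list-column of label vectors).
#' @export
enumerate_paths <- function(tree, params, renormalize = FALSE) {
  stopifnot(inherits(tree, "strategy_tree"))
  env <- list2env(parameter_values(params), parent = baseenv())
  out <- list()
  walk <- function(cn, prob, cost, effect, labels) {
    cost <- cost + eval_expr(cn$cost, env, "cost payload", cn$label)
    effect <- effect + eval_expr(cn$effect, env, "effect payload", cn$label)
    labels <- c(labels, cn$label)
    if (cn$kind == "terminal" || length(cn$branches) == 0) {
      out[[length(out) + 1L]] <<- list(prob = prob, cost = cost, effect = effect, labels = labels)
      return(invisible())
    }
    p <- branch_probs(cn, env, renormalize)
    for (i in seq_along(cn$branches)) {
      walk(cn$branches[[i]]$node, prob * p[i], cost, effect, labels)
    }
  }
  walk(compile_tree(tree$root), 1, 0, 0, character(0))
  tibble::tibble(
    path_probability = vapply(out, `[[`, numeric(1), "prob"),
    path_cost = vapply(out, `[[`, numeric(1), "cost"),
    path_effect = vapply(out, `[[`, numeric(1), "effect"),
    node_labels = lapply(out, `[[`, "labels")
  )
}

#' Validate a strategy tree against a parameter set
#'
#' Structural and probabilistic invariants checked at base parameter
#' values. An empty result means the tree is valid.
#'
#' @inheritParams rollback
#' @return A tibble of diagnostics: `node`, `rule`, `message`, `fatal`.
#'   Zero rows iff the tree satisfies every invariant.
#' @export
validate_tree <- function(tree, params) {
  stopifnot(inherits(tree, "strategy_tree"))
  env <- list2env(parameter_values(params), parent = baseenv())
  diags <- list()
  note <- function(node, rule, message, fatal = FALSE) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      node = node, rule = rule, message = message, fatal = fatal
    )
  }
  check_expr <- function(chr, node, what) {
    lang <- tryCatch(str2lang(chr), error = function(e) NULL)
    if (is.null(lang)) {
      note(node, "unparseable_expression", paste0(what, " '", chr, "' cannot be parsed"), fatal = TRUE)
      return(NULL)
    }
    missing <- setdiff(all.vars(lang), ls(env))
    if (length(missing) > 0) {
      note(node, "unknown_parameter",
           paste0(what, " '", chr, "' references unknown parameter(s): ",
                  paste(missing, collapse = ", ")), fatal = TRUE)
      return(NULL)
    }
    eval(lang, envir = env)
  }
  walk <- function(n, depth) {
    if (!n$kind %in% c("decision", "chance", "terminal")) {
      note(n$label, "unknown_kind", paste0("unknown node kind '", n$kind, "'"), fatal = TRUE)
      return(invisible())
    }
    if (n$kind == "decision" && depth > 0) {
      note(n$label, "decision_not_root", "decision nodes may appear only at the root")
    }
    if (n$kind == "terminal" && length(n$branches) > 0) {
      note(n$label, "terminal_has_branches", "terminal nodes must have no branches")
    }
    check_expr(n$cost, n$label, "cost payload")
    check_expr(n$effect, n$label, "effect payload")
    if (n$kind == "chance") {
      if (length(n$branches) == 0) {
        note(n$label, "chance_no_branches", "chance node has no branches")
      } else {
        probs <- numeric(0)
        ok <- TRUE
        for (b in n$branches) {
          if (is.null(b$prob)) {
            note(n$label, "missing_probability", "chance-node branch lacks a probability", fatal = TRUE)
            ok <- FALSE
          } else {
            v <- check_expr(b$prob, n$label, "branch probability")
            if (is.null(v)) ok <- FALSE else probs <- c(probs, v)
          }
        }
        if (ok) {
          out <- probs < -1e-9 | probs > 1 + 1e-9
          if (any(out)) {
            note(n$label, "probability_range",
                 paste0("branch probability ", format(probs[which(out)[1]]), " outside [0, 1]"))
          }
          if (abs(sum(probs) - 1) > 1e-9) {
            note(n$label, "probability_sum",
                 paste0("branch probabilities sum to ", format(sum(probs)), ", expected 1"))
          }
        }
      }
    }
    if (n$kind == "decision") {
      for (b in n$branches) {
        if (!is.null(b$prob)) {
          note(n$label, "decision_branch_probability",
               "decision-node branches must not carry probabilities")
        }
      }
    }
    for (b in n$branches) walk(b$node, depth + 1)
  }
  walk(tree$root, 0)
  if (tree$effect_mode == "scalar_override" &&
      (!is_number(tree$scalar_effect) || tree$scalar_effect < 0)) {
    note("<root>", "scalar_effect", "scalar effect override must be a non-negative number")
  }
  if (length(diags) == 0) {
    tibble::tibble(node = character(0), rule = character(0),
                   message = character(0), fatal = logical(0))
  } else {
    dplyr::bind_rows(diags)
  }
}
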