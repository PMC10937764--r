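#' Read an NHS reference-cost table
#'
#' Comma-separated with header `code,descriptor,unit_cost_gbp`, optionally
#' preceded by an `item` column giving a unique short key. The `item`
#' column exists because HRG codes are setting-dependent and may repeat
#' within one table (e.g. LB09D prices both non-elective stenting and
#' outpatient stent removal); uniqueness is enforced on `item` when
#' present, on `code` otherwise. Currency symbols and thousands separators
#' in the cost column are stripped (`"£7,202.79"` reads as 7202.79) and
#' en-dashes in code ranges are normalised to hyphens.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `cost_table` with columns (`item`,) `code`,
#'   `descriptor`, `unit_cost_gbp`.
#' @seealso [cost_value()]
#' @export
read_cost_table <- function(path) {
  if (!file.exists(path)) abort_stonecea(paste0("cost table not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("code", "descriptor", "unit_cost_gbp")
  if (!all(needed %in% names(raw))) {
    abort_stonecea(paste0("cost table ", path, " must have columns ",
                          paste(needed, collapse = ", ")))
  }
  raw$code <- gsub("–|—", "-", raw$code)
  cost <- as.numeric(gsub("[£,[:space:]]", "", raw$unit_cost_gbp))
  if (anyNA(cost)) {
    bad <- raw$code[is.na(cost)]
    abort_stonecea(paste0("unparseable unit cost for code(s): ", paste(bad, collapse = ", ")))
  }
  if (any(cost < 0)) {
    bad <- raw$code[cost < 0]
    abort_stonecea(paste0("negative unit cost for code(s): ", paste(bad, collapse = ", ")))
  }
  raw$unit_cost_gbp <- cost
  key <- if ("item" %in% names(raw)) raw$item else raw$code
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort_stonecea(paste0("duplicate cost-table key(s): ", paste(dup, collapse = ", ")))
  }
  keep <- intersect(c("item", "code", "descriptor", "unit_cost_gbp"), names(raw))
  out <- tibble::as_tibble(raw[keep])
  class(out) <- c("cost_table", class(out))
  out
}

#' Look up a unit cost
#'
#' @param table A [read_cost_table()] result.
#' @param key The `item` key if the table has one, else the HRG `code`.
#' @return The unit cost in GBP. Unknown keys are an error.
#' @export
cost_value <- function(table, key) {
  keys <- if ("item" %in% names(table)) table$item else table$code
  i <- match(key, keys)
  if (anyNA(i)) {
    abort_stonecea(paste0("unknown cost-table key(s): ", paste(key[is.na(i)], collapse = ", ")))
  }
  table$unit_cost_gbp[i]
}

# ---- model config (YAML) ------------------------------------------------

node_to_list <- function(n) {
  out <- list(kind = n$kind, label = n$label)
  if (n$cost != "0") out$cost <- n$cost
  if (n$effect != "0") out$effect <- n$effect
  if (length(n$branches) > 0) {
    out$branches <- lapply(n$branches, function(b) {
      bl <- list()
      if (!is.null(b$prob)) bl$prob <- b$prob
      bl$node <- node_to_list(b$node)
      bl
    })
  }
  out
}

node_from_list <- function(x) {
  branches <- lapply(x$branches %||% list(), function(b) {
    branch(b$prob %||% NULL, node_from_list(b$node))
  })
  n <- structure(
    list(kind = x$kind, label = x$label,
         cost = as_expr_chr(x$cost %||% 0, "cost"),
         effect = as_expr_chr(x$effect %||% 0, "effect"),
         branches = branches),
    class = "tree_node"
  )
  n
}

#' Write / read a decision-model configuration
#'
#' Serialises a model (parameters, strategy trees with expression payloads,
#' scalar effect overrides, calibration targets, reference/comparator) as a
#' structured key-value document (YAML, `schema: 1`). Writing then reading
#' reproduces the model exactly.
#'
#' @param model A model list as returned by [stone_model()].
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns the model list.
#' @export
write_model_config <- function(model, path) {
  doc <- list(
    schema = 1L,
    reference = model$reference,
    comparator = model$comparator,
    parameters = lapply(seq_len(nrow(model$params)), function(i) {
      p <- model$params[i, ]
      list(name = p$name, role = p$role, value = p$value, free = p$free,
           lower = if (is.finite(p$lower)) p$lower else ".inf",
           upper = if (is.finite(p$upper)) p$upper else ".inf")
    }),
    strategies = lapply(model$trees, function(tr) {
      s <- list(strategy = tr$strategy)
      if (tr$effect_mode == "scalar_override") s$scalar_effect <- tr$scalar_effect
      s$root <- node_to_list(tr$root)
      s
    }),
    calibration_targets = as.list(model$targets)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort_stonecea(paste0("model config not found: ", path))
  doc <- yaml::read_yaml(path)
  if (!identical(as.integer(doc$schema %||% -1L), 1L)) {
    abort_stonecea(paste0("unsupported model config schema: ", doc$schema %||% "<missing>"))
  }
  to_num <- function(x) if (identical(x, ".inf")) Inf else as.numeric(x)
  params <- dplyr::bind_rows(lapply(doc$parameters, function(p) {
    parameter(p$name, p$role, as.numeric(p$value), free = isTRUE(p$free),
              lower = to_num(p$lower), upper = to_num(p$upper))
  }))
  trees <- lapply(doc$strategies, function(s) {
    strategy_tree(s$strategy, node_from_list(s$root),
                  scalar_effect = s$scalar_effect %||% NULL)
  })
  targets <- unlist(doc$calibration_targets)
  list(
    trees = trees,
    params = as_parameter_set(params),
    targets = targets,
    reference = doc$reference,
    comparator = doc$comparator
  )
}

# ---- pipeline -----------------------------------------------------------

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_stonecea(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
                   class = "stonecea_pipeline_error", parent = e)
  })
}

#' Run the full cost-effectiveness pipeline
#'
#' validate -> calibrate -> evaluate -> ICER -> sensitivity -> reports.
#' Takes either an in-memory model (from [stone_model()] or
#' [read_model_config()]) or a run-configuration list/YAML path naming a
#' `model_file`. Reports are written to `output_dir` when given:
#' `evaluation.csv`, `cea.csv`, `sensitivity.csv`, `tornado.csv`,
#' `summary.csv` (the published-table layout, rounded), and
#' `pipeline.log`. All failures are conditions that name the failing
#' stage.
#'
#' @param config A run-configuration list or YAML path with fields
#'   `model_file` (path), optional `cost_table_files` (paths),
#'   `sensitivity_fraction` (in (0, 0.5], default 0.1), optional
#'   `currency_rate` (EUR/GBP), optional `output_dir`, optional
#'   `log_level` (`"quiet"` or `"info"`). Alternatively pass a model list
#'   directly (fields `trees`, `params`, ...) plus the other settings as
#'   arguments.
#' @param model Optional in-memory model overriding `model_file`.
#' @param sensitivity_fraction,currency_rate,output_dir,log_level
#'   Overrides for the corresponding config fields.
#' @return A list of class `cea_pipeline`: `evaluation`, `cea`,
#'   `sensitivity`, `tornado`, `summary`, `calibration`, `params`.
#' @export
run_pipeline <- function(config = list(), model = NULL,
                         sensitivity_fraction = NULL, currency_rate = NULL,
                         output_dir = NULL, log_level = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_stonecea(paste0("run config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config$trees)) {  # a model was passed as `config`
    model <- config
    config <- list()
  }
  fraction <- sensitivity_fraction %||% config$sensitivity_fraction %||% 0.1
  rate <- currency_rate %||% config$currency_rate %||% NULL
  output_dir <- output_dir %||% config$output_dir %||% NULL
  log_level <- log_level %||% config$log_level %||% "quiet"
  if (!is_number(fraction) || fraction <= 0 || fraction > 0.5) {
    abort_stonecea("sensitivity_fraction must lie in (0, 0.5]")
  }
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (identical(log_level, "info")) message(line)
  }

  cost_tables <- with_stage("read_cost_tables", {
    lapply(config$cost_table_files %||% character(0), read_cost_table)
  })
  if (length(cost_tables) > 0) say("read ", length(cost_tables), " cost table(s)")

  if (is.null(model)) {
    if (is.null(config$model_file)) abort_stonecea("no model given: supply `model` or config$model_file")
    model <- with_stage("read_model", read_model_config(config$model_file))
    say("read model from ", config$model_file)
  }

  with_stage("validate", {
    for (tr in model$trees) {
      d <- validate_tree(tr, model$params)
      if (nrow(d) > 0) {
        abort_stonecea(paste0(
          "strategy '", tr$strategy, "' failed validation: ",
          paste(paste0("[", d$rule, "] ", d$node, ": ", d$message), collapse = "; ")
        ))
      }
    }
  })
  say("validated ", length(model$trees), " strategy tree(s)")

  params <- model$params
  calibration <- NULL
  if (!is.null(model$targets) && length(model$targets) > 0) {
    params <- with_stage("calibrate",
      calibrate_free_parameters(model$trees, params, model$targets))
    calibration <- attr(params, "calibration")
    say("calibrated free parameters (max residual ",
        format(max(abs(calibration$residual))), " GBP)")
  }

  evaluation <- with_stage("evaluate", evaluate_strategies(model$trees, params))
  cea <- with_stage("icer",
    compare_strategies(evaluation, model$reference, model$comparator))
  sens <- with_stage("sensitivity",
    joint_range(model$trees, params, fraction = fraction,
                reference = model$reference, comparator = model$comparator))
  torn <- with_stage("sensitivity",
    tornado(model$trees, params, fraction = fraction, quantity = "icer",
            reference = model$reference, comparator = model$comparator))
  summary_tbl <- render_reports(evaluation, cea, sens, currency_rate = rate)
  say("ICER ", format(round_half_up(cea$icer)), " GBP per inpatient-day averted (",
      cea$dominance, ")")

  if (!is.null(output_dir)) {
    with_stage("write_reports", {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(evaluation, file.path(output_dir, "evaluation.csv"))
      readr::write_csv(tibble::as_tibble(unclass(cea)), file.path(output_dir, "cea.csv"))
      readr::write_csv(tibble::as_tibble(unclass(sens)), file.path(output_dir, "sensitivity.csv"))
      readr::write_csv(tibble::as_tibble(unclass(torn)), file.path(output_dir, "tornado.csv"))
      readr::write_csv(summary_tbl, file.path(output_dir, "summary.csv"))
      writeLines(log_lines, file.path(output_dir, "pipeline.log"))
    })
  }

  structure(
    list(evaluation = evaluation, cea = cea, sensitivity = sens, tornado = torn,
         summary = summary_tbl, calibration = calibration, params = params,
         cost_tables = cost_tables, log = log_lines),
    class = "cea_pipeline"
  )
}

#' @export
print.cea_pipeline <- function(x, ...) {
  cat("<cea_pipeline>\n")
  print(x$summary)
  invisible(x)
}

#' Summary report in the published-table layout
#'
#' One row per strategy: expected cost with its joint sensitivity interval,
#' mean inpatient days, and (on the reference row) the ICER with its
#' interval. Costs and ICERs are rounded half-up to the nearest GBP; when a
#' currency rate is supplied, parallel EUR columns are added.
#'
#' @param evaluation Tibble from [evaluate_strategies()].
#' @param cea A [compute_icer()] result.
#' @param sensitivity Optional tibble from [joint_range()]; when absent the
#'   interval columns are `NA`.
#' @param currency_rate Optional EUR per GBP.
#' @return A tibble: `strategy`, `expected_cost_gbp`, `cost_low_gbp`,
#'   `cost_high_gbp`, `inpatient_days`, `icer_gbp_per_day`, `icer_low_gbp`,
#'   `icer_high_gbp` (and `*_eur` columns when a rate is given).
#' @export
render_reports <- function(evaluation, cea, sensitivity = NULL, currency_rate = NULL) {
  rows <- lapply(seq_len(nrow(evaluation)), function(i) {
    s <- evaluation$strategy[i]
    lo <- hi <- NA_real_
    if (!is.null(sensitivity)) {
      m <- sensitivity$quantity == "expected_cost" & sensitivity$strategy == s
      if (any(m)) { lo <- sensitivity$low[which(m)[1]]; hi <- sensitivity$high[which(m)[1]] }
    }
    is_ref <- identical(s, cea$reference)
    ilo <- ihi <- icer <- NA_real_
    if (is_ref) {
      icer <- cea$icer
      if (!is.null(sensitivity)) {
        m <- sensitivity$quantity == "icer"
        if (any(m)) { ilo <- sensitivity$low[which(m)[1]]; ihi <- sensitivity$high[which(m)[1]] }
      }
    }
    tibble::tibble(
      strategy = s,
      expected_cost_gbp = round_half_up(evaluation$expected_cost[i]),
      cost_low_gbp = round_half_up(lo), cost_high_gbp = round_half_up(hi),
      inpatient_days = evaluation$expected_effect[i],
      icer_gbp_per_day = round_half_up(icer),
      icer_low_gbp = round_half_up(ilo), icer_high_gbp = round_half_up(ihi)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(currency_rate)) {
    for (col in c("expected_cost_gbp", "cost_low_gbp", "cost_high_gbp", "icer_gbp_per_day")) {
      eur_col <- sub("_gbp.*$", "_eur", col)
      out[[eur_col]] <- convert_currency(out[[col]], rate = currency_rate, round_to = 0)
    }
  }
  out
}
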