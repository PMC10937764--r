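#' Synthetic two-arm cohort configuration
#'
#' Defaults describe the study conditions the analysis assumes: 100
#' patients treated by emergency ureteroscopic laser fragmentation (EUL)
#' and 20 by emergency stenting with delayed ureteroscopy (DUL);
#' normally-distributed ages; right-skewed, non-negative stone sizes,
#' lengths of stay and detection-to-treatment intervals drawn from Gamma
#' distributions moment-matched to the published means and SDs; stone
#' locations at the published shares; and independent Bernoulli secondary
#' outcomes at the published rates.
#'
#' @param n_eul,n_dul Arm sizes.
#' @param arms A two-element named list (`EUL`, `DUL`); each element a list
#'   with `age = c(mean, sd)`, `stone_size = c(mean, sd)` (mm),
#'   `los = c(mean, sd)` (days), `detection_to_treatment = c(mean, sd)`
#'   (days), `male` (share), `location` (named shares over
#'   proximal/mid/distal summing to 1), `outcomes` (named probabilities
#'   for complication, clearance, re_intervention, re_admission,
#'   follow_up_imaging).
#' @param duration_dist `"gamma"` (default) or `"lognormal"` for the
#'   skewed positive variables.
#' @param seed Integer seed used by [generate_cohort()] unless overridden.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_eul = 100, n_dul = 20, arms = NULL,
                          duration_dist = c("gamma", "lognormal"), seed = 1L) {
  duration_dist <- match.arg(duration_dist)
  default_arms <- list(
    EUL = list(
      age = c(55.66, 17.7), stone_size = c(8.24, 4.46),
      los = c(3.76, 7.14), detection_to_treatment = c(2.13, 5.7),
      male = 0.73,
      location = c(proximal = 0.33, mid = 0.16, distal = 0.51),
      outcomes = c(complication = 0.04, clearance = 0.66, re_intervention = 0.09,
                   re_admission = 0.18, follow_up_imaging = 0.30)
    ),
    DUL = list(
      age = c(66.73, 14.8), stone_size = c(10.12, 4.72),
      los = c(6.11, 5.20), detection_to_treatment = c(91.63, 50.6),
      male = 0.55,
      location = c(proximal = 0.40, mid = 0.35, distal = 0.25),
      outcomes = c(complication = 0.05, clearance = 0.70, re_intervention = 0.15,
                   re_admission = 0.20, follow_up_imaging = 0.90)
    )
  )
  arms <- arms %||% default_arms
  cfg <- structure(
    list(n_eul = as.integer(n_eul), n_dul = as.integer(n_dul), arms = arms,
         duration_dist = duration_dist, seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_eul < 0 || cfg$n_dul < 0) abort_stonecea("arm sizes must be non-negative")
  for (arm in c("EUL", "DUL")) {
    a <- cfg$arms[[arm]]
    if (is.null(a)) abort_stonecea(paste0("missing arm configuration: ", arm))
    if (abs(sum(a$location) - 1) > 1e-9) {
      abort_stonecea(paste0("location shares for arm ", arm, " must sum to 1"))
    }
    probs <- c(a$outcomes, a$male, a$location)
    if (any(probs < 0 | probs > 1)) {
      abort_stonecea(paste0("probabilities for arm ", arm, " must lie in [0, 1]"))
    }
    sds <- c(a$age[2], a$stone_size[2], a$los[2], a$detection_to_treatment[2])
    if (any(sds < 0)) abort_stonecea(paste0("standard deviations for arm ", arm, " must be >= 0"))
  }
  invisible(cfg)
}

# moment-matched right-skewed draw (gamma by default); floor truncates below
rskewed <- function(n, mean, sd, dist = "gamma", floor = 0) {
  if (n == 0) return(numeric(0))
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  if (dist == "gamma") {
    shape <- (mean / sd)^2
    if (shape < 0.01) {
      abort_stonecea(sprintf(
        "infeasible moments: mean %.3g with sd %.3g gives Gamma shape %.3g < 0.01",
        mean, sd, shape
      ))
    }
    x <- stats::rgamma(n, shape = shape, rate = mean / sd^2)
  } else {
    sdlog2 <- log(1 + (sd / mean)^2)
    x <- stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }
  pmax(x, floor)
}

#' Generate a synthetic patient-level cohort
#'
#' Draws `n_eul + n_dul` patient records per the configuration:
#' ages Normal; stone sizes and durations Gamma (or lognormal)
#' moment-matched to the configured mean/SD, stone sizes truncated below
#' at 0.1 mm; locations categorical; sex and the five secondary outcomes
#' independent Bernoulli. Reproducible for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer; overrides `config$seed`. `NULL` uses the config's.
#' @return A tibble with one row per patient: `patient_id`, `arm`, `age`,
#'   `sex`, `stone_size_mm`, `location`, `los_days`,
#'   `detection_to_treatment_days`, and logical `complication`,
#'   `clearance`, `re_intervention`, `re_admission`, `follow_up_imaging`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, arm)
generate_cohort <- function(config, seed = NULL) {
  validate_cohort_config(config)
  seed <- seed %||% config$seed
  gen <- function() {
    one_arm <- function(arm, n) {
      a <- config$arms[[arm]]
      if (n == 0) return(NULL)
      tibble::tibble(
        arm = arm,
        age = stats::rnorm(n, a$age[1], a$age[2]),
        sex = ifelse(stats::runif(n) < a$male, "M", "F"),
        stone_size_mm = rskewed(n, a$stone_size[1], a$stone_size[2],
                                config$duration_dist, floor = 0.1),
        location = sample(names(a$location), n, replace = TRUE, prob = a$location),
        los_days = rskewed(n, a$los[1], a$los[2], config$duration_dist, floor = 0),
        detection_to_treatment_days = rskewed(n, a$detection_to_treatment[1],
                                              a$detection_to_treatment[2],
                                              config$duration_dist, floor = 0),
        complication = stats::runif(n) < a$outcomes[["complication"]],
        clearance = stats::runif(n) < a$outcomes[["clearance"]],
        re_intervention = stats::runif(n) < a$outcomes[["re_intervention"]],
        re_admission = stats::runif(n) < a$outcomes[["re_admission"]],
        follow_up_imaging = stats::runif(n) < a$outcomes[["follow_up_imaging"]]
      )
    }
    out <- dplyr::bind_rows(one_arm("EUL", config$n_eul), one_arm("DUL", config$n_dul))
    if (is.null(out) || nrow(out) == 0) {
      out <- tibble::tibble(
        arm = character(0), age = numeric(0), sex = character(0),
        stone_size_mm = numeric(0), location = character(0),
        los_days = numeric(0), detection_to_treatment_days = numeric(0),
        complication = logical(0), clearance = logical(0),
        re_intervention = logical(0), re_admission = logical(0),
        follow_up_imaging = logical(0)
      )
    }
    dplyr::mutate(out, patient_id = dplyr::row_number(), .before = 1)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

outcome_fields <- c("complication", "clearance", "re_intervention",
                    "re_admission", "follow_up_imaging")

#' Estimate model parameters from a patient-level cohort
#'
#' Per-arm empirical proportions for each boolean outcome and means/SDs
#' for the continuous fields, returned both as a summary table and as a
#' [parameter_set()] fragment whose names match the decision model
#' (`p_<outcome>_<arm>`, `los_<arm>`), ready for [update_parameters()].
#'
#' @param cohort A tibble as produced by [generate_cohort()].
#' @return A list with `params` (parameter-set fragment) and `summary`
#'   (tibble: `arm`, `variable`, `type`, `n`, `estimate`, `sd`).
#' @export
estimate_parameters <- function(cohort) {
  for (arm in c("EUL", "DUL")) {
    if (!any(cohort$arm == arm)) {
      abort_stonecea(paste0("cohort has no patients in arm ", arm))
    }
  }
  cont_fields <- c("age", "stone_size_mm", "los_days", "detection_to_treatment_days")
  summaries <- purrr::map(c("EUL", "DUL"), function(arm) {
    d <- dplyr::filter(cohort, .data$arm == !!arm)
    props <- purrr::map(outcome_fields, function(f) {
      tibble::tibble(arm = arm, variable = f, type = "proportion",
                     n = nrow(d), estimate = mean(d[[f]]), sd = NA_real_)
    })
    male <- tibble::tibble(arm = arm, variable = "male", type = "proportion",
                           n = nrow(d), estimate = mean(d$sex == "M"), sd = NA_real_)
    conts <- purrr::map(cont_fields, function(f) {
      tibble::tibble(arm = arm, variable = f, type = "continuous",
                     n = nrow(d), estimate = mean(d[[f]]), sd = stats::sd(d[[f]]))
    })
    locs <- purrr::map(c("proximal", "mid", "distal"), function(loc) {
      tibble::tibble(arm = arm, variable = paste0("location_", loc), type = "proportion",
                     n = nrow(d), estimate = mean(d$location == loc), sd = NA_real_)
    })
    dplyr::bind_rows(c(props, list(male), conts, locs))
  })
  summary_tbl <- dplyr::bind_rows(summaries)

  frag <- dplyr::bind_rows(purrr::map(c("EUL", "DUL"), function(arm) {
    s <- dplyr::filter(summary_tbl, .data$arm == !!arm)
    low <- tolower(arm)
    probs <- dplyr::bind_rows(purrr::map(outcome_fields, function(f) {
      parameter(paste0("p_", f, "_", low), "probability",
                s$estimate[s$variable == f])
    }))
    los <- parameter(paste0("los_", low), "duration_days",
                     s$estimate[s$variable == "los_days"])
    dplyr::bind_rows(probs, los)
  }))
  list(params = as_parameter_set(frag), summary = summary_tbl)
}

#' End-to-end consistency check of the synthetic pipeline
#'
#' Generates a cohort, re-estimates outcome probabilities and mean lengths
#' of stay from it, injects the estimates into the decision model, rolls
#' the trees back, and compares the plug-in results with the rollback at
#' the exact configured probabilities. With large arms the two must agree
#' closely (sample proportions are unbiased and the expected cost is
#' continuous in the parameters).
#'
#' @param config A [cohort_config()]; consider `n_eul = n_dul = 10000` for
#'   a tight check.
#' @param model A decision model as returned by [stone_model()]: a list
#'   with `trees`, `params`, `targets`, `reference`, `comparator`.
#' @param seed Integer; overrides `config$seed`.
#' @param calibrate If `TRUE` (default), free parameters are first
#'   calibrated to the model's cost targets.
#' @return A list of class `stonecea_e2e`: `comparison` (tibble with
#'   exact vs plug-in expected costs and relative differences per
#'   strategy), `cea_exact`, `cea_plugin` (both [compute_icer()] results),
#'   and `estimates` (the [estimate_parameters()] output).
#' @export
end_to_end_check <- function(config = cohort_config(), model = stone_model(),
                             seed = NULL, calibrate = TRUE) {
  params <- model$params
  if (calibrate) {
    params <- calibrate_free_parameters(model$trees, params, model$targets)
  }
  exact_eval <- evaluate_strategies(model$trees, params)
  cea_exact <- compare_strategies(exact_eval, model$reference, model$comparator)

  cohort <- generate_cohort(config, seed = seed)
  est <- estimate_parameters(cohort)
  plug_params <- update_parameters(params, est$params)
  plug_trees <- purrr::map(model$trees, function(tr) {
    low <- tolower(tr$strategy)
    los_row <- est$params[est$params$name == paste0("los_", low), ]
    if (nrow(los_row) == 1 && tr$effect_mode == "scalar_override") {
      tr$scalar_effect <- los_row$value
    }
    tr
  })
  plug_eval <- evaluate_strategies(plug_trees, plug_params, renormalize = TRUE)
  cea_plugin <- compare_strategies(plug_eval, model$reference, model$comparator)

  comparison <- dplyr::left_join(
    dplyr::rename(exact_eval, cost_exact = "expected_cost", effect_exact = "expected_effect"),
    dplyr::rename(plug_eval, cost_plugin = "expected_cost", effect_plugin = "expected_effect"),
    by = "strategy"
  )
  comparison$cost_rel_diff <- abs(comparison$cost_plugin - comparison$cost_exact) /
    comparison$cost_exact
  structure(
    list(comparison = comparison, cea_exact = cea_exact, cea_plugin = cea_plugin,
         estimates = est),
    class = "stonecea_e2e"
  )
}

#' @export
print.stonecea_e2e <- function(x, ...) {
  cat("<stonecea_e2e> plug-in vs exact rollback\n")
  print(x$comparison)
  cat("ICER (exact):  ", format(x$cea_exact$icer), " GBP/day averted, ",
      x$cea_exact$dominance, "\n", sep = "")
  cat("ICER (plug-in):", format(x$cea_plugin$icer), " GBP/day averted, ",
      x$cea_plugin$dominance, "\n", sep = "")
  invisible(x)
}

#' Read and write patient-level cohorts as CSV
#'
#' Plain-text serialization of the tibble produced by
#' [generate_cohort()]; writing then reading is lossless up to floating
#' point text representation.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_stonecea(paste0("cohort file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_integer(),
    arm = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    stone_size_mm = readr::col_double(),
    location = readr::col_character(),
    los_days = readr::col_double(),
    detection_to_treatment_days = readr::col_double(),
    complication = readr::col_logical(),
    clearance = readr::col_logical(),
    re_intervention = readr::col_logical(),
    re_admission = readr::col_logical(),
    follow_up_imaging = readr::col_logical()
  ))
}
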