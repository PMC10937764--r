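#' Bundled NHS reference-cost tables
#'
#' The unit-cost schedules used by the EUL/DUL comparison (NHS reference
#' costs 2019–2020, keyed by HRG code). The DUL table carries an `item`
#' key column because HRG code LB09D prices both non-elective stenting and
#' outpatient stent removal.
#'
#' @return A list of two `cost_table` tibbles, `EUL` and `DUL`.
#' @export
#' @examples
#' stone_cost_tables()$EUL
stone_cost_tables <- function() {
  list(
    EUL = read_cost_table(system.file("extdata", "eul_costs.csv", package = "stonecea")),
    DUL = read_cost_table(system.file("extdata", "dul_costs.csv", package = "stonecea"))
  )
}

#' Parameter set for the EUL vs DUL comparison
#'
#' Unit costs come from the bundled reference-cost tables; the inpatient
#' per-diem is £262/bed-day; event probabilities are the observed cohort
#' rates (re-admission 18%/20%, re-intervention 9%/15%, follow-up imaging
#' needed in 30%/90%). Quantities the publication does not pin down —
#' the share of EUL patients left with a stent, the ultrasound-vs-CT split
#' of follow-up imaging, and the mean re-admission and re-intervention
#' episode costs — are free parameters with clinically-motivated bounds,
#' resolved by [calibrate_free_parameters()] against the published
#' per-strategy totals. Re-admission episode cost is bounded between a
#' non-admitted follow-up attendance (WF02C) and two inpatient days plus a
#' diagnostic cystoscopy; re-intervention episode cost between the
#' cheapest (ESWL) and dearest (PCNL, CC 2+) plausible modality.
#'
#' @param cost_tables Output of [stone_cost_tables()].
#' @param daily_bed_cost Inpatient cost per bed-day in GBP.
#' @return A [parameter_set()].
#' @export
stone_parameters <- function(cost_tables = stone_cost_tables(), daily_bed_cost = 262) {
  eul <- cost_tables$EUL
  dul <- cost_tables$DUL
  readm_lo <- cost_value(eul, "WF02C")
  readm_hi <- 2 * daily_bed_cost + cost_value(eul, "LB72A")
  reint_lo <- cost_value(eul, "LB36Z")
  reint_hi <- cost_value(eul, "LB75A")
  parameter_set(
    parameter("daily_bed_cost", "daily_cost", daily_bed_cost),
    parameter("los_eul", "duration_days", 3.76),
    parameter("los_dul", "duration_days", 6.11),
    parameter("cost_eul_ureteroscopy", "unit_cost", cost_value(eul, "LB65C-LB65E")),
    parameter("cost_emergency_stenting", "unit_cost", cost_value(dul, "emergency_stenting")),
    parameter("cost_elective_ureteroscopy", "unit_cost", cost_value(dul, "elective_ureteroscopy")),
    parameter("cost_stent_removal", "unit_cost", cost_value(eul, "LB09D")),
    parameter("cost_us_eul", "unit_cost", cost_value(eul, "RD40Z-RD42Z")),
    parameter("cost_us_dul", "unit_cost", cost_value(dul, "ultrasound")),
    parameter("cost_ct", "unit_cost", cost_value(eul, "RD23Z")),
    parameter("p_follow_up_imaging_eul", "probability", 0.30),
    parameter("p_follow_up_imaging_dul", "probability", 0.90),
    parameter("p_re_admission_eul", "probability", 0.18),
    parameter("p_re_admission_dul", "probability", 0.20),
    parameter("p_re_intervention_eul", "probability", 0.09),
    parameter("p_re_intervention_dul", "probability", 0.15),
    parameter("p_stent_insitu_eul", "probability", 0.5, free = TRUE),
    parameter("p_imaging_us_eul", "probability", 0.5, free = TRUE),
    parameter("p_imaging_us_dul", "probability", 0.5, free = TRUE),
    parameter("cost_re_admission_episode_eul", "unit_cost", (readm_lo + readm_hi) / 2,
              free = TRUE, lower = readm_lo, upper = readm_hi),
    parameter("cost_re_admission_episode_dul", "unit_cost", (readm_lo + readm_hi) / 2,
              free = TRUE, lower = readm_lo, upper = readm_hi),
    parameter("cost_re_intervention_episode_eul", "unit_cost", (reint_lo + reint_hi) / 2,
              free = TRUE, lower = reint_lo, upper = reint_hi),
    parameter("cost_re_intervention_episode_dul", "unit_cost", (reint_lo + reint_hi) / 2,
              free = TRUE, lower = reint_lo, upper = reint_hi)
  )
}

# shared downstream event chain: clearance assessment -> imaging modality
# -> re-admission -> re-intervention
stone_event_chain <- function(arm, label, cost) {
  reint_node <- function(lbl, cost) {
    chance_node(lbl, cost = cost,
      branch(paste0("p_re_intervention_", arm),
             terminal_node(paste0(lbl, ": re-intervention"),
                           cost = paste0("cost_re_intervention_episode_", arm))),
      branch(paste0("1 - p_re_intervention_", arm),
             terminal_node(paste0(lbl, ": no re-intervention")))
    )
  }
  readm_node <- function(lbl, cost) {
    chance_node(lbl, cost = cost,
      branch(paste0("p_re_admission_", arm),
             reint_node(paste0(lbl, ": re-admitted"),
                        cost = paste0("cost_re_admission_episode_", arm))),
      branch(paste0("1 - p_re_admission_", arm),
             reint_node(paste0(lbl, ": no re-admission"), cost = 0))
    )
  }
  chance_node(label, cost = cost,
    branch(paste0("p_follow_up_imaging_", arm),
      chance_node(paste0(label, ": follow-up imaging"),
        branch(paste0("p_imaging_us_", arm),
               readm_node(paste0(label, ": ultrasound"),
                          cost = paste0("cost_us_", arm))),
        branch(paste0("1 - p_imaging_us_", arm),
               readm_node(paste0(label, ": CT"), cost = "cost_ct"))
      )),
    branch(paste0("1 - p_follow_up_imaging_", arm),
           readm_node(paste0(label, ": clearance confirmed intra-operatively"), cost = 0))
  )
}

#' Strategy trees for the EUL vs DUL comparison
#'
#' EUL: one emergency admission covering ureteroscopic laser fragmentation
#' and the inpatient stay; a chance the patient leaves with a stent
#' (outpatient removal later); then clearance assessment (intra-operative
#' confirmation vs follow-up ultrasound/CT), possible re-admission, and
#' possible re-intervention. DUL: emergency stenting plus a later elective
#' ureteroscopy and stent removal form the deterministic backbone, then
#' the same event chain with the DUL rates. Effects are the cohort mean
#' inpatient durations, supplied as scalar overrides.
#'
#' @param effects Named numeric: mean inpatient days per strategy.
#' @return A list of two [strategy_tree()] objects.
#' @export
stone_trees <- function(effects = c(EUL = 3.76, DUL = 6.11)) {
  eul_root <- chance_node(
    "EUL index admission",
    cost = "cost_eul_ureteroscopy + los_eul * daily_bed_cost",
    branch("p_stent_insitu_eul",
           stone_event_chain("eul", "stent in situ", cost = "cost_stent_removal")),
    branch("1 - p_stent_insitu_eul",
           stone_event_chain("eul", "no stent", cost = 0))
  )
  dul_root <- stone_event_chain(
    "dul", "DUL admissions (stenting, elective ureteroscopy, stent removal)",
    cost = paste("cost_emergency_stenting + cost_elective_ureteroscopy +",
                 "cost_stent_removal + los_dul * daily_bed_cost")
  )
  list(
    strategy_tree("EUL", eul_root, scalar_effect = effects[["EUL"]]),
    strategy_tree("DUL", dul_root, scalar_effect = effects[["DUL"]])
  )
}

#' The bundled EUL vs DUL decision model
#'
#' Trees, parameters and calibration targets for the comparison of
#' emergency ureteroscopic laser fragmentation (EUL) against emergency
#' stenting with delayed ureteroscopy (DUL). The per-strategy expected-cost
#' targets are the published totals (£4915 EUL, £7783 DUL); calibrating the
#' free parameters to them and rolling back reproduces the comparison.
#'
#' @param targets Named numeric calibration targets in GBP.
#' @return A list: `trees`, `params`, `targets`, `reference` (`"EUL"`),
#'   `comparator` (`"DUL"`).
#' @seealso [run_pipeline()], [calibrate_free_parameters()]
#' @export
#' @examples
#' \donttest{
#' model <- stone_model()
#' params <- calibrate_free_parameters(model$trees, model$params, model$targets)
#' evaluate_strategies(model$trees, params)
#' }
stone_model <- function(targets = c(EUL = 4915, DUL = 7783)) {
  list(
    trees = stone_trees(),
    params = stone_parameters(),
    targets = targets,
    reference = "EUL",
    comparator = "DUL"
  )
}

#' Bundled two-arm comparison table
#'
#' The cohort characteristics and secondary outcomes of the two arms
#' (counts, means, SDs and the p-values as published), in the input format
#' of [cohort_comparison_table()]. Arm 1 is EUL (n = 100), arm 2 DUL
#' (n = 20).
#'
#' @return A tibble with columns `label`, `type`, `x1`, `n1`, `x2`, `n2`,
#'   `mean1`, `sd1`, `mean2`, `sd2`, `published_p`.
#' @export
stone_comparisons <- function() {
  readr::read_csv(
    system.file("extdata", "cohort_comparisons.csv", package = "stonecea"),
    col_types = readr::cols(
      label = readr::col_character(), type = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
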