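# stonecea

Decision-tree cost-effectiveness analysis for acute ureteric stone
management: emergency ureteroscopic laser fragmentation (**EUL**) versus
emergency temporising JJ-stent insertion followed by delayed elective
ureteroscopy (**DUL**).

## What it does, and for whom

For health economists and urology service planners asking whether
treating an obstructing ureteric stone definitively at the first
admission is cheaper than stenting and rescheduling. The package
provides:

* a **decision-tree engine**: chance/terminal nodes whose payloads and
  branch probabilities are expressions over named parameters; expected
  cost by leaves-to-root rollback,
  `E[C] = c(node) + Σᵢ pᵢ E[Cᵢ]`,
  with a path-enumeration oracle (`Σ_paths P(path)·C(path)`) as the
  independent cross-check;
* **calibration**: quantities the published tables do not pin down
  (stent-in-situ probability, ultrasound/CT imaging split, re-admission
  and re-intervention episode costs) are free parameters with bounds,
  solved by per-parameter bisection until the rolled-back totals match
  the published per-strategy costs within £1;
* **ICER and dominance**: `ICER = (C_DUL − C_EUL) / (E_DUL − E_EUL)` in
  GBP per inpatient-day averted, with dominance flagged when one
  strategy is cheaper and no worse;
* **deterministic ±10% sensitivity analysis**: one-way tornado ranges
  and joint box ranges over all cost and probability parameters — exact
  vertex enumeration for up to 13 varied parameters (expected cost is
  multilinear, so extremes sit at vertices), deterministic coordinate
  endpoint search beyond that; the ICER is evaluated as a ratio at
  candidate points, never as independent numerator/denominator extremes;
* **cohort statistics**: pooled two-proportion z-tests (no continuity
  correction) and summary-statistic t-tests (pooled or Welch)
  reproducing the published two-arm comparison tables;
* a **synthetic cohort generator**: two arms (100 EUL / 20 DUL by
  default) with Normal ages, moment-matched Gamma stone sizes, lengths
  of stay and detection-to-treatment intervals, and Bernoulli secondary
  outcomes at the observed rates, plus parameter re-estimation and an
  end-to-end plug-in consistency check;
* NHS reference-cost table I/O, a YAML model-configuration format, and a
  one-call `run_pipeline()` that validates, calibrates, evaluates,
  compares, runs the sensitivity analysis and writes the reports.

## Worked example

```r
library(stonecea)

model  <- stone_model()           # trees, parameters, calibration targets
params <- calibrate_free_parameters(model$trees, model$params, model$targets)
evaluate_strategies(model$trees, params)
#> # A tibble: 2 × 3
#>   strategy expected_cost expected_effect
#>   <chr>            <dbl>           <dbl>
#> 1 EUL              4915.            3.76
#> 2 DUL              7783.            6.11

cea <- compare_strategies(evaluate_strategies(model$trees, params), "EUL", "DUL")
glance(cea)
#> # A tibble: 1 × 4
#>   delta_cost delta_effect  icer dominance
#>        <dbl>        <dbl> <dbl> <chr>
#> 1      2868.         2.35 1220. reference_dominates

joint_range(model$trees, params, fraction = 0.10)
#> # A tibble: 3 × 9
#>   quantity      strategy    base   low  high fraction n_varied method
#> 1 expected_cost EUL        4915. 4375. 5466.      0.1       12 vertex
#> 2 expected_cost DUL        7783. 6887. 8705.      0.1       12 vertex
#> 3 icer          EUL vs DUL 1220.  699. 1750.      0.1       21 coordinate_desce…
```

Read: the emergency pathway costs £4915 per patient against £7783 for
stent-then-delayed surgery, saving £2868 per patient while also averting
2.35 inpatient days — EUL *dominates* (cheaper and better), and the ICER
of £1220 per inpatient-day averted stays positive across the whole ±10%
joint variation of costs and probabilities.

The published arm comparisons:

```r
cohort_comparison_table(stone_comparisons())[c(5, 6, 7), c("label", "p_value_3dp")]
#>   share_proximal_ureteric_stones  0.547
#>   share_mid_ureteric_stones       0.049
#>   share_distal_ureteric_stones    0.033
```

And the synthetic pipeline:

```r
e2e <- end_to_end_check(cohort_config(n_eul = 10000, n_dul = 10000, seed = 7))
e2e$comparison[, c("strategy", "cost_exact", "cost_plugin", "cost_rel_diff")]
#>   EUL  4915.  4904.  0.0022
#>   DUL  7783.  7814.  0.0040
```

See `vignettes/stonecea-methods.Rmd` for the model, its assumptions, the
calibration bounds and every numerical convention.

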