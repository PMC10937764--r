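---
title: "Decision-tree cost-effectiveness of emergency versus delayed ureteroscopy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-effectiveness of emergency versus delayed ureteroscopy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonecea)
```

## The decision problem

An adult presenting with an acute, CT-confirmed obstructing ureteric stone
can be treated in two ways at the first admission:

* **EUL** — emergency ureteroscopy with laser fragmentation: definitive
  treatment during the index admission, with a chance that a temporary JJ
  stent is left in situ and removed later as an outpatient procedure;
* **DUL** — emergency temporising JJ-stent insertion, followed by a
  delayed (elective) ureteroscopy with laser fragmentation and a
  subsequent stent removal: at least two hospital admissions.

Clinical effectiveness of the two pathways is similar (single-procedure
stone-free rates around 85%), so the economic question dominates: what
does each pathway cost the health service per patient, and what is the
incremental cost per inpatient-day averted? `stonecea` implements a
single-episode decision-tree model of this comparison, the associated
incremental cost-effectiveness ratio (ICER) and dominance analysis, a
deterministic ±10% sensitivity analysis, the two-arm cohort comparison
statistics, and a synthetic patient-level cohort generator that lets the
whole pipeline run and be tested without access to patient data.

## The decision tree

Each strategy is a finite tree of chance and terminal nodes. Node
payloads (costs in GBP, effects in days) and branch probabilities are
expressions over named parameters, e.g.
`"cost_eul_ureteroscopy + los_eul * daily_bed_cost"`. The expected cost
of a strategy is the standard leaves-to-root rollback: a terminal node
contributes its payload; a chance node contributes its payload plus the
probability-weighted sum of its children. `enumerate_paths()` provides
the brute-force oracle — every root-to-terminal path with its probability
and accumulated payload — against which the rollback recursion is tested
to 1e-9 relative tolerance on randomly generated trees (depth up to 5,
branching up to 4).

The bundled model (`stone_model()`) gives both strategies the same event
chain after the index procedure(s):

1. **Index admission(s)** — EUL: the non-elective ureteroscopy HRG cost
   plus the mean inpatient stay (3.76 days) at £262/bed-day; DUL: the
   non-elective stenting, elective ureteroscopy and stent-removal HRG
   costs plus its stay (6.11 days at £262/day).
2. **Stent in situ?** (EUL only) — with a free probability the patient
   leaves with a stent, adding the outpatient stent-removal cost; the DUL
   pathway always includes stent removal in its backbone.
3. **Clearance assessment** — clearance confirmed intra-operatively, or
   follow-up imaging (30% of EUL patients, 90% of DUL patients, the
   observed cohort shares); imaging splits between ultrasound and CT with
   a free mixing probability.
4. **Re-admission** within 3 months — at the observed rates 18% (EUL)
   and 20% (DUL), adding a free per-episode cost.
5. **Re-intervention** — at 9% and 15%, adding a free per-episode cost.

Effects are the cohort mean inpatient durations (3.76 vs 6.11 days),
attached as per-strategy scalar overrides rather than accumulated along
the tree, because the comparison measures effect as mean inpatient days
against those cohort means.

## Calibration of free parameters

Four kinds of quantity are not pinned down by the published tables: the
EUL stent-in-situ probability, the ultrasound/CT split of follow-up
imaging, and the mean re-admission and re-intervention episode costs. They
are `free` parameters with clinically motivated bounds:

* imaging split and stent probability: the full \[0, 1\] range;
* re-admission episode: between a non-admitted follow-up attendance
  (WF02C, £77.56) and two inpatient days plus a diagnostic cystoscopy
  (£695.38). The lower end represents the re-admissions that are really
  re-attendances for stent symptoms; the upper end an admission with
  endoscopic assessment — the cohort definition of re-admission
  explicitly includes elective admissions for further management, so an
  episode can exceed a single bed-day;
* re-intervention episode: between the cheapest plausible modality (ESWL,
  £331.20) and the dearest (percutaneous nephrolithotomy at CC 2+,
  £7202.79). The single free cost is the *expectation* of the modality
  mix — equivalent in expected value to a free simplex over the
  modalities, with one calibration dimension instead of three.

`calibrate_free_parameters()` adjusts each strategy's free parameters
until the rolled-back expected cost matches the published per-strategy
totals (£4915 EUL, £7783 DUL). Expected cost is *multilinear* — affine in
each parameter holding the others fixed — so each free parameter is
solved by bisection on its monotone one-dimensional restriction, and the
parameters are cycled until the residual falls below £1 (at most 100
cycles; in practice one or two suffice). Attainability is verified first
by computing the expected-cost range over the free-parameter box; an
out-of-range target errors with the attainable `[min, max]`. Calibration
is idempotent: re-running it moves no parameter by more than £0.01
equivalent.

The calibrated model is a *faithful reconstruction*, not a transcription:
the published figure of the tree does not print its branch probabilities,
so the free quantities are resolved against the published totals rather
than copied. Consequently the model reproduces the totals, the
incremental cost (£2868) and the ICER (£1220/day averted) exactly, while
its sensitivity intervals are structurally comparable to, but not
numerically identical with, the published ones.

## ICER and dominance

`compute_icer()` reports `delta_cost = cost_cmp − cost_ref`,
`delta_effect = effect_cmp − effect_ref` (inpatient days averted by the
reference) and their ratio. Dominance is flagged when one strategy is
strictly cheaper with no worse effect; the ICER is still reported under
dominance, matching the usual table presentation. A zero effect
difference yields no ICER (`NA`), never an infinity.

## Deterministic sensitivity analysis

All *cost* and *probability* parameters are varied by ±10%
(`fraction = 0.10`); durations are not varied, so the ICER denominator
stays at its cohort value. Two observations justify this: the published
table prints no interval for inpatient days, and the published ICER
interval is exactly the cost-interval envelope divided by the fixed
2.35-day difference. A perturbed probability is clipped to \[0, 1\]; its
two-branch complement (written `1 − p`) follows automatically, and nodes
with three or more branches are proportionally renormalised at evaluation
time, so conservation holds at every perturbed point.

* `one_way_range()` evaluates the target quantity at the two endpoints of
  one parameter's interval. By multilinearity the extremes over the whole
  interval lie at those endpoints (verified against a 21-point grid scan
  in the tests). `tornado()` ranks all parameters by swing.
* `joint_range()` varies the whole set jointly over the ±10% box. For a
  multilinear function the extremes lie at the box's vertices, so with
  `k ≤ max_vertex_params` (default 13) all `2^k` vertices are enumerated
  — exact, and about 4,000–8,000 rollbacks per strategy for the bundled
  model (k = 12 per strategy). For larger k (the ICER varies the union of
  both trees' parameters, k = 21) a deterministic coordinate-wise
  endpoint descent/ascent from five fixed starting patterns is used; on
  this model it reproduces the exact vertex optimum because the
  delta-cost is coordinate-monotone over the box, and the tests compare
  the two routes directly. The base point is always evaluated, so every
  reported interval contains its base value, and intervals at a smaller
  fraction nest inside those at a larger one.
* The ICER range is obtained by evaluating the *ratio* at candidate
  points — never by independently optimising numerator and denominator,
  which would overstate the interval. If the effect difference changes
  sign inside the box, the range is reported over the feasible-sign
  subset with a warning flag.

## Cohort comparison statistics

Categorical outcomes are compared with the pooled two-proportion z-test
without continuity correction; this is the test that reproduces the
published stone-location p-values (0.033 distal, 0.049 mid-ureteric) from
the printed counts, where Fisher's exact test and the continuity-corrected
chi-square do not. It equals the square root of the uncorrected
chi-square, and the suite cross-checks it against
`prop.test(correct = FALSE)` and a direct normal-CDF recomputation on
1,000 random tables. Continuous characteristics use the two-sample t-test
computed from summary statistics (mean, SD, n), pooled-variance by
default — closest to the published age p-value (0.010 computed vs 0.011
printed from the rounded summaries) — with Welch available by flag.
Degenerate variances are flagged rather than silently propagated. One
published p-value (0.048 for the share of males) is not reproducible by
any standard two-sample proportion test on the printed counts (pooled z
gives 0.109); the package reports the recomputed value and makes no
attempt to force agreement. Reported p-values are rounded half-up to 3
decimals alongside the exact values.

## The synthetic cohort generator

`generate_cohort()` emulates the two study arms: 100 EUL and 20 DUL
patients by default, Normal ages, and Gamma-distributed stone sizes,
lengths of stay and detection-to-treatment intervals moment-matched to
the published means and SDs. Gamma was chosen because these quantities
are non-negative and right-skewed, and in places the SD exceeds the mean
(EUL detection-to-treatment 2.13 ± 5.7 days), which a shape < 1 Gamma
represents naturally; a lognormal alternative is available via
`duration_dist = "lognormal"`. Moments with Gamma shape below 0.01 are
rejected as infeasible. Stone sizes are truncated below at 0.1 mm. The
five secondary outcomes are independent Bernoulli draws at the configured
rates — the study reports only marginal rates, so no joint structure is
imposed; this is a documented limitation (real complications,
re-admissions and re-interventions are correlated). Sex is generated at
the observed shares but not used downstream (no sex-specific costs).

`estimate_parameters()` recovers per-arm rates and moments from a cohort
in the shape the decision model consumes, and `end_to_end_check()` closes
the loop: generate → estimate → inject → roll back → compare with the
exact-probability rollback. With 10,000 patients per arm the plug-in
expected costs land within a fraction of a percent of the exact ones;
the test suite asserts the 5% bound together with 3-binomial-SE recovery
of every outcome probability. What passing these checks shows is
*internal consistency* of the pipeline — not that the generator
reproduces real patient data, whose correlation structure, censoring and
cost heterogeneity it deliberately omits.

## Numerical conventions

* Rollback vs oracle agreement: 1e-9 relative; probability conservation
  at chance nodes: 1e-9.
* Calibration: residual tolerance £1 (achieved ~1e-9), bisection to 80
  iterations per parameter, at most 100 parameter cycles.
* Vertex/grid agreement in the sensitivity tests: 1e-6 relative.
* Report rounding: costs and ICERs half-up to the nearest £1, p-values
  half-up to 3 decimals (`round_half_up()`, since `base::round()` uses
  round-half-even); all internal computation is unrounded.
* Currency: all computation in GBP; EUR is a display conversion with a
  configurable rate (default 1.1367 EUR/GBP, representative of the
  2019–2020 reference-cost year).
* Unknown parameter names are always an error, never a silent default.

Problem sizes used by the test suite and the acceptance script: 100
random trees for the oracle property; 2^12-vertex enumerations per
strategy and a 21-parameter coordinate search for the ICER in the joint
sensitivity; 10,000 patients per arm for parameter recovery; 1,000 random
tables for the z-test oracle.

## Design choices where the ground truth is open

* **Tree topology.** The published tree figure is an image without
  printed numbers; the reconstruction keeps every event class the
  publication names (stent in situ, clearance vs imaging, ultrasound/CT,
  re-admission, re-intervention) and admits the unprinted numbers as free
  calibrated parameters rather than guessing point values.
* **Re-admission episode cost bound.** The upper bound is two bed-days
  plus a diagnostic cystoscopy. One bed-day plus cystoscopy would make
  the £7783 DUL total unattainable (the attainable maximum is then
  £7756), and the cohort's own definition of re-admission includes
  elective admissions for further management, so the wider bound is the
  clinically defensible choice.
* **Ultrasound cost discrepancy.** The two published cost tables price
  the same ultrasound code at £65.64 and £65.54; each strategy uses the
  value from its own table, and both fixtures preserve their table
  verbatim.
* **Two-day pre-operative stay.** Whether the ~2-day wait between CT
  detection and emergency ureteroscopy is costed inside the 3.76-day EUL
  mean is not stated; the model takes the printed mean at face value and
  adds nothing on top.
* **Interface.** Users of an analysis package like this work in R, so
  the exported functions (with `run_pipeline()` as the one-call driver)
  are the interface; there is no shell executable.

## Worked example

```{r example, eval = FALSE}
model <- stone_model()
params <- calibrate_free_parameters(model$trees, model$params, model$targets)
evaluate_strategies(model$trees, params)
#>   strategy expected_cost expected_effect
#>   EUL              4915.            3.76
#>   DUL              7783.            6.11

res <- run_pipeline(model)
res$summary
glance(res$cea)   # delta_cost 2868, icer 1220.4, reference_dominates
autoplot(res$sensitivity)
autoplot(res$tornado)
```

## Known limitations

* Single acute episode: no Markov/state-transition structure, no
  discounting, no multi-year horizon.
* No quality-of-life weighting — the effect axis is inpatient days, not
  QALYs, because no QoL data exist for these cohorts.
* Deterministic sensitivity only; no probabilistic (Monte Carlo)
  sensitivity analysis or CEACs, matching the source analysis.
* The published sensitivity intervals cannot be reproduced exactly
  because the varied-parameter set and the tree's internal numbers are
  unprinted; the package asserts containment, nesting and
  vertex-optimality properties instead, and its intervals come out close
  to the published ones.
* The cohort comparison is 100 vs 20 patients from one centre; the
  synthetic generator reproduces its marginals, not patient-level
  dependence.
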