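test_that("a degenerate single-terminal tree is valid and rolls back to its payload", {
  tr <- strategy_tree("t", terminal_node("only", cost = 100), scalar_effect = 0)
  expect_identical(nrow(validate_tree(tr, empty_params())), 0L)
  expect_equal(rollback(tr, empty_params())$expected_cost, 100)
  paths <- enumerate_paths(tr, empty_params())
  expect_identical(nrow(paths), 1L)
  expect_equal(paths$path_probability, 1)
})

test_that("validation flags non-conserving branch probabilities", {
  tr <- strategy_tree("t", chance_node(
    "bad",
    branch(0.7, terminal_node("a")),
    branch(0.2, terminal_node("b"))
  ), scalar_effect = 0)
  d <- validate_tree(tr, empty_params())
  expect_identical(nrow(d), 1L)
  expect_identical(d$rule, "probability_sum")
  expect_match(d$message, "sum to 0.9")
  expect_error(rollback(tr, empty_params()), class = "stonecea_probability_error")
})

test_that("validation reports unresolvable parameter names as fatal", {
  tr <- strategy_tree("t", chance_node(
    "c",
    branch("p_missing", terminal_node("a")),
    branch("1 - p_missing", terminal_node("b"))
  ), scalar_effect = 0)
  d <- validate_tree(tr, empty_params())
  expect_true(any(d$rule == "unknown_parameter" & d$fatal))
  expect_match(d$message[d$rule == "unknown_parameter"][1], "p_missing")
  expect_error(rollback(tr, empty_params()), class = "stonecea_unknown_parameter")
})

test_that("the bundled strategy trees satisfy every invariant at base values", {
  m <- stone_model()
  for (tr in m$trees) {
    expect_identical(nrow(validate_tree(tr, m$params)), 0L)
  }
})

test_that("the DUL deterministic backbone alone sums the published cost items", {
  # stenting 1850.90 + elective ureteroscopy 2854.44 + stent removal 171.42
  # + 6.11 inpatient days at 262/day
  ps <- parameter_set(
    parameter("cost_emergency_stenting", "unit_cost", 1850.90),
    parameter("cost_elective_ureteroscopy", "unit_cost", 2854.44),
    parameter("cost_stent_removal", "unit_cost", 171.42),
    parameter("los_dul", "duration_days", 6.11),
    parameter("daily_bed_cost", "daily_cost", 262)
  )
  tr <- strategy_tree("DUL_backbone", terminal_node(
    "index admissions",
    cost = paste("cost_emergency_stenting + cost_elective_ureteroscopy +",
                 "cost_stent_removal + los_dul * daily_bed_cost")
  ), scalar_effect = 6.11)
  expect_equal(rollback(tr, ps)$expected_cost, 6477.58, tolerance = 1e-12)
})

test_that("a balanced binary chance tree of depth 2 yields four equiprobable paths", {
  half <- function(a, b) chance_node("flip", branch(0.5, a), branch(0.5, b))
  tr <- strategy_tree("sym", half(
    half(terminal_node("aa", cost = 1), terminal_node("ab", cost = 2)),
    half(terminal_node("ba", cost = 3), terminal_node("bb", cost = 4))
  ), scalar_effect = 0)
  paths <- enumerate_paths(tr, empty_params())
  expect_identical(nrow(paths), 4L)
  expect_equal(paths$path_probability, rep(0.25, 4))
  expect_equal(rollback(tr, empty_params())$expected_cost, 2.5)
})

test_that("rollback agrees with the path-enumeration oracle on random trees", {
  withr::local_seed(101)
  for (i in 1:60) {
    tr <- random_tree(depth = sample(2:5, 1), max_branch = 4)
    rb <- rollback(tr, empty_params())
    pe <- enumerate_paths(tr, empty_params())
    expect_equal(sum(pe$path_probability), 1, tolerance = 1e-9)
    expect_equal(sum(pe$path_probability * pe$path_cost), rb$expected_cost,
                 tolerance = 1e-9)
    expect_equal(sum(pe$path_probability * pe$path_effect), rb$expected_effect,
                 tolerance = 1e-9)
  }
})

test_that("expected cost is monotone non-decreasing in every unit cost", {
  m <- stone_model()
  base <- evaluate_strategies(m$trees, m$params)
  cost_params <- m$params$name[m$params$role %in% c("unit_cost", "daily_cost")]
  for (tr in m$trees) {
    for (p in intersect(cost_params, tree_parameters(tr))) {
      up <- perturb_parameters(m$params, p, +0.10)
      expect_gte(
        rollback(tr, up)$expected_cost,
        base$expected_cost[base$strategy == tr$strategy]
      )
    }
  }
})

test_that("expected cost is affine in each parameter (three-point collinearity)", {
  m <- stone_model()
  tr <- m$trees[[1]]
  withr::local_seed(11)
  for (p in sample(tree_parameters(tr), 6)) {
    v0 <- get_parameter(m$params, p)$value
    v1 <- v0 * 1.1 + 0.01
    f <- function(v) rollback(tr, set_parameter(m$params, p, v, clamp = FALSE))$expected_cost
    expect_equal(f((v0 + v1) / 2), (f(v0) + f(v1)) / 2, tolerance = 1e-9)
  }
})

test_that("tree_parameters finds every referenced name", {
  m <- stone_model()
  nm <- tree_parameters(m$trees[[1]])
  expect_true(all(c("cost_eul_ureteroscopy", "p_stent_insitu_eul",
                    "daily_bed_cost", "cost_re_intervention_episode_eul") %in% nm))
  expect_false("cost_emergency_stenting" %in% nm)
})
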