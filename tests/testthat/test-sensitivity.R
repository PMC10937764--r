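test_that("a pass-through cost parameter gives the trivial one-way interval", {
  ps <- parameter_set(parameter("c", "unit_cost", 100))
  tr <- strategy_tree("t", terminal_node("leaf", cost = "c"), scalar_effect = 1)
  r <- one_way_range(tr, ps, "c", fraction = 0.1)
  expect_equal(r$low_result, 90)
  expect_equal(r$high_result, 110)
  expect_equal(r$swing, 20)
})

test_that("an unreferenced parameter has zero swing", {
  ps <- parameter_set(
    parameter("c", "unit_cost", 100),
    parameter("unused", "unit_cost", 50)
  )
  tr <- strategy_tree("t", terminal_node("leaf", cost = "c"), scalar_effect = 1)
  expect_equal(one_way_range(tr, ps, "unused", fraction = 0.1)$swing, 0)
  expect_error(one_way_range(tr, ps, "ghost", 0.1), class = "stonecea_unknown_parameter")
})

test_that("one-way endpoints bracket a dense grid scan over the interval", {
  m <- stone_model()
  cal <- calibrate_free_parameters(m$trees, m$params, m$targets)
  tr <- m$trees[[1]]
  # widen bounds so the grid scan may leave the calibration box
  wide <- cal
  wide$free <- FALSE
  wide$lower <- ifelse(wide$role == "probability", 0, -Inf)
  wide$upper <- ifelse(wide$role == "probability", 1, Inf)
  wide <- as_parameter_set(wide)
  withr::local_seed(3)
  for (p in sample(tree_parameters(tr), 4)) {
    r <- one_way_range(tr, cal, p, fraction = 0.1)
    v0 <- get_parameter(cal, p)$value
    grid <- seq(v0 * 0.9, v0 * 1.1, length.out = 21)
    if (get_parameter(cal, p)$role == "probability") grid <- pmin(pmax(grid, 0), 1)
    vals <- vapply(grid, function(v) {
      rollback(tr, set_parameter(wide, p, v), renormalize = TRUE)$expected_cost
    }, numeric(1))
    expect_lte(min(c(r$low_result, r$high_result)), min(vals) + 1e-9)
    expect_gte(max(c(r$low_result, r$high_result)), max(vals) - 1e-9)
  }
})

test_that("the tornado table is sorted by descending swing", {
  m <- stone_model()
  cal <- calibrate_free_parameters(m$trees, m$params, m$targets)
  tt <- tornado(m$trees[[1]], cal, fraction = 0.1)
  expect_true(all(diff(tt$swing) <= 1e-12))
  expect_true(all(tt$swing >= 0))
  # biggest single driver of EUL expected cost is the index procedure cost
  expect_identical(tt$parameter[1], "cost_eul_ureteroscopy")
  expect_s3_class(plot_tornado(tt), "ggplot")
})

test_that("vertex enumeration matches a dense grid on a two-parameter toy tree", {
  toy <- toy_two_param()
  jr <- joint_range(list(toy$tree), toy$params, fraction = 0.1, reference = NA)
  grid <- expand.grid(
    p = seq(0.27, 0.33, length.out = 11),
    c = seq(450, 550, length.out = 11)
  )
  vals <- apply(grid, 1, function(g) {
    ps <- set_parameter(toy$params, c("p_hit", "c_hit"), g)
    rollback(toy$tree, ps, renormalize = TRUE)$expected_cost
  })
  expect_equal(jr$low, min(vals), tolerance = 1e-6)
  expect_equal(jr$high, max(vals), tolerance = 1e-6)
  expect_identical(jr$method, "vertex")
})

test_that("a single pass-through parameter gives the trivial joint interval", {
  ps <- parameter_set(parameter("c", "unit_cost", 100))
  tr <- strategy_tree("t", terminal_node("leaf", cost = "c"), scalar_effect = 1)
  jr <- joint_range(list(tr), ps, fraction = 0.1, reference = NA)
  expect_equal(jr$low, 90)
  expect_equal(jr$high, 110)
})

test_that("coordinate descent agrees with vertex enumeration when both apply", {
  m <- stone_model()
  cal <- calibrate_free_parameters(m$trees, m$params, m$targets)
  exact <- joint_range(list(m$trees[[1]]), cal, fraction = 0.1, reference = NA,
                       max_vertex_params = 13)
  descent <- joint_range(list(m$trees[[1]]), cal, fraction = 0.1, reference = NA,
                         max_vertex_params = 2)
  expect_identical(descent$method, "coordinate_descent")
  expect_equal(descent$low, exact$low, tolerance = 1e-9)
  expect_equal(descent$high, exact$high, tolerance = 1e-9)
})

test_that("joint ranges contain the base case and respect the varied-parameter switch", {
  m <- stone_model()
  cal <- calibrate_free_parameters(m$trees, m$params, m$targets)
  jr <- joint_range(m$trees, cal, fraction = 0.1)
  expect_true(all(jr$low <= jr$base + 1e-9 & jr$base <= jr$high + 1e-9))
  expect_false(any(jr$denominator_sign_change))
  jr_cost <- joint_range(list(m$trees[[1]]), cal, fraction = 0.1,
                         vary = "costs", reference = NA)
  jr_all <- joint_range(list(m$trees[[1]]), cal, fraction = 0.1, reference = NA)
  expect_lt(jr_cost$n_varied, jr_all$n_varied)
  expect_gte(jr_cost$low, jr_all$low - 1e-9)
  expect_lte(jr_cost$high, jr_all$high + 1e-9)
  expect_s3_class(plot_sensitivity_ranges(jr), "ggplot")
})

test_that("an ICER denominator sign change is flagged and the feasible subset reported", {
  # tree-accumulated effects whose difference crosses zero inside the box
  ps <- parameter_set(
    parameter("c_a", "unit_cost", 100),
    parameter("e_a", "duration_days", 5),
    parameter("e_b_extra", "unit_cost", 0.3)  # varied; flips the effect sign
  )
  tr_a <- strategy_tree("A", terminal_node("a", cost = "c_a", effect = "e_a"))
  tr_b <- strategy_tree("B", terminal_node("b", cost = 120,
                                           effect = "e_a - 0.25 + e_b_extra"))
  expect_warning(
    jr <- joint_range(list(tr_a, tr_b), ps, fraction = 0.2,
                      reference = "A", comparator = "B"),
    "changes sign"
  )
  icer_row <- jr[jr$quantity == "icer", ]
  expect_true(icer_row$denominator_sign_change)
  expect_true(is.finite(icer_row$low) && is.finite(icer_row$high))
})

test_that("invalid fractions are rejected", {
  toy <- toy_two_param()
  expect_error(one_way_range(toy$tree, toy$params, "p_hit", fraction = 0), "fraction")
  expect_error(joint_range(list(toy$tree), toy$params, fraction = 1.2), "fraction")
})
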