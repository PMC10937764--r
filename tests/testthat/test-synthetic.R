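test_that("cohort configuration validates shares and probabilities", {
  expect_s3_class(cohort_config(), "cohort_config")
  bad <- cohort_config()
  bad$arms$EUL$location <- c(proximal = 0.5, mid = 0.4, distal = 0.4)
  expect_error(validate_cohort_config(bad), "sum to 1")
  bad2 <- cohort_config()
  bad2$arms$DUL$outcomes[["re_admission"]] <- 1.2
  expect_error(generate_cohort(bad2), "\\[0, 1\\]")
})

test_that("an empty configuration yields an empty cohort", {
  cohort <- generate_cohort(cohort_config(n_eul = 0, n_dul = 0))
  expect_identical(nrow(cohort), 0L)
  expect_true(all(c("arm", "los_days", "re_admission") %in% names(cohort)))
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 123))
  b <- generate_cohort(cohort_config(seed = 123))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a, c_))
})

test_that("generated cohorts respect arm sizes, positivity, and binomial bounds", {
  cohort <- generate_cohort(cohort_config(seed = 42))
  expect_identical(nrow(cohort), 120L)
  expect_identical(sum(cohort$arm == "EUL"), 100L)
  expect_true(all(cohort$stone_size_mm >= 0.1))
  expect_true(all(cohort$los_days >= 0))
  expect_true(all(cohort$detection_to_treatment_days >= 0))
  # Binomial(100, 0.18) lies in [5, 32] except with probability < 1e-3
  n_readm <- sum(cohort$re_admission[cohort$arm == "EUL"])
  expect_gte(n_readm, 5)
  expect_lte(n_readm, 32)
})

test_that("infeasible Gamma moments are rejected", {
  cfg <- cohort_config()
  cfg$arms$EUL$detection_to_treatment <- c(0.1, 10)  # shape 1e-4
  expect_error(generate_cohort(cfg), "infeasible moments")
})

test_that("moment matching reproduces the configured mean and sd at scale", {
  withr::local_seed(8)
  x <- stonecea:::rskewed(1e5, 3.76, 7.14)
  expect_equal(mean(x), 3.76, tolerance = 0.02)
  expect_equal(sd(x), 7.14, tolerance = 0.05)
  y <- stonecea:::rskewed(1e5, 91.63, 50.6, dist = "lognormal")
  expect_equal(mean(y), 91.63, tolerance = 0.02)
  expect_equal(sd(y), 50.6, tolerance = 0.05)
})

test_that("estimated parameters recover configured rates at 1/sqrt(n)", {
  cfg <- cohort_config(n_eul = 10000, n_dul = 10000, seed = 31)
  est <- estimate_parameters(generate_cohort(cfg))
  for (arm in c("EUL", "DUL")) {
    truth <- cfg$arms[[arm]]$outcomes
    for (f in names(truth)) {
      got <- est$params$value[est$params$name == paste0("p_", f, "_", tolower(arm))]
      se <- sqrt(truth[[f]] * (1 - truth[[f]]) / 10000)
      expect_lt(abs(got - truth[[f]]), 3 * se + 1e-12)
    }
  }
  # convergence rate: error shrinks roughly as 1/sqrt(n) across decades
  err_at <- function(n, seed) {
    e <- estimate_parameters(generate_cohort(cohort_config(n, n, seed = seed)))
    abs(e$params$value[e$params$name == "p_re_admission_eul"] - 0.18)
  }
  errs <- vapply(1:20, function(s) err_at(100, s), numeric(1))
  errs_big <- vapply(1:20, function(s) err_at(10000, s), numeric(1))
  expect_lt(mean(errs_big), mean(errs))
})

test_that("a fully-observed outcome estimates probability one", {
  cohort <- generate_cohort(cohort_config(n_eul = 50, n_dul = 5, seed = 1))
  cohort$re_admission[cohort$arm == "EUL"] <- TRUE
  est <- estimate_parameters(cohort)
  expect_equal(est$params$value[est$params$name == "p_re_admission_eul"], 1)
})

test_that("an empty arm is reported by name", {
  cohort <- generate_cohort(cohort_config(n_eul = 10, n_dul = 0, seed = 1))
  expect_error(estimate_parameters(cohort), "arm DUL")
})

test_that("small-sample re-admission estimates are unbiased across seeds", {
  rates <- vapply(1:100, function(s) {
    cohort <- generate_cohort(cohort_config(n_eul = 20, n_dul = 20, seed = 1000 + s))
    mean(cohort$re_admission[cohort$arm == "EUL"])
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.18), 0.02)
})

test_that("cohort CSV round-trip is lossless", {
  cohort <- generate_cohort(cohort_config(n_eul = 30, n_dul = 10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12)
})

test_that("end-to-end plug-in rollback tracks the exact-probability rollback", {
  e2e <- end_to_end_check(cohort_config(n_eul = 10000, n_dul = 10000, seed = 7))
  expect_true(all(e2e$comparison$cost_rel_diff < 0.05))
  expect_identical(e2e$cea_plugin$dominance, e2e$cea_exact$dominance)
  expect_identical(sign(e2e$cea_plugin$icer), sign(e2e$cea_exact$icer))
})

test_that("a degenerate all-zero configuration collapses to the procedure backbone", {
  cfg <- cohort_config(n_eul = 200, n_dul = 50, seed = 9)
  for (arm in c("EUL", "DUL")) {
    cfg$arms[[arm]]$outcomes[] <- 0
    cfg$arms[[arm]]$los <- c(0, 0)
  }
  m <- stone_model()
  m$params <- set_parameter(m$params, "p_stent_insitu_eul", 0)
  e2e <- end_to_end_check(cfg, m, calibrate = FALSE)
  eul_cost <- e2e$comparison$cost_plugin[e2e$comparison$strategy == "EUL"]
  expect_equal(eul_cost, 3402.12, tolerance = 1e-9)
  dul_cost <- e2e$comparison$cost_plugin[e2e$comparison$strategy == "DUL"]
  expect_equal(dul_cost, 1850.90 + 2854.44 + 171.42, tolerance = 1e-9)
})
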