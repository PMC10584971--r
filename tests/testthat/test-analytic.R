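test_that("midpoint collapse halves every range", {
  pt <- midpoint_parameters(ivf_parameters())
  expect_equal(pt$fresh$rfsh_myoins$oocyte_pickup, 0.75)
  expect_equal(pt$fresh$rfsh$oocyte_pickup, 0.75)
  expect_equal(pt$fresh$rfsh_myoins$icsi_share, 0.30)
  expect_equal(pt$costs$pickup_ultrasound, 30)  # degenerate range -> itself
  expect_equal(pt$sequence$start_cycle3_after_failure, 0.45)
})

test_that("fresh-cycle pregnancy matches the path enumeration and frozen constants", {
  pt <- midpoint_parameters(ivf_parameters())
  for (arm in ivf_strategies()) {
    enum <- enum_fresh_paths(pt, arm)
    expect_equal(sum(enum$prob), 1, tolerance = 1e-12)
    expect_equal(expected_fresh_pregnancy(pt, arm),
                 sum(enum$prob * enum$pregnant), tolerance = 1e-12)
  }
  # frozen-in values recomputed by the enumeration oracle at table midpoints
  expect_equal(expected_fresh_pregnancy(pt, "rfsh_myoins"), 0.1281013,
               tolerance = 1e-6)
  expect_equal(expected_fresh_pregnancy(pt, "rfsh"), 0.1083591,
               tolerance = 1e-6)
  # frozen cycle: survival x pregnancy-after-survival
  expect_equal(ivfcea:::frozen_cycle_values(pt)$pregnancy, 0.95 * 0.325)
})

test_that("the recursive tree evaluation agrees with the flat enumeration to machine precision", {
  points <- c(list(ivf_parameters()), lapply(c(7, 8, 9, 10), random_scenario))
  for (params in points) {
    pt <- midpoint_parameters(params)
    for (arm in ivf_strategies()) {
      enum <- enum_program_expectations(pt, arm)
      got <- expected_program_outcomes(pt, arm)
      expect_equal(enum$total_prob, 1, tolerance = 1e-12)
      expect_equal(got$pregnancy, enum$pregnancy, tolerance = 1e-12)
      expect_equal(got$expected_cost, enum$expected_cost, tolerance = 1e-10)
      expect_equal(got$expected_cycles, enum$expected_cycles, tolerance = 1e-12)
      expect_equal(got$expected_fresh_cycles, enum$expected_fresh_cycles,
                   tolerance = 1e-12)
    }
  }
})

test_that("a single certain path yields probability one at its exact item total", {
  pt <- midpoint_parameters(certain_success_midpoint_costs())
  out <- expected_program_outcomes(pt, "rfsh_myoins")
  expect_equal(out$pregnancy, 1)
  expect_equal(out$expected_cost, FORCED_IVF_PATH_COST)
  expect_equal(out$cost_per_pregnancy, FORCED_IVF_PATH_COST)
  expect_equal(out$expected_cycles, 1)
})

test_that("zero continuation reduces the program to a single fresh cycle exactly", {
  pt <- midpoint_parameters(ivf_parameters())
  pt$sequence$start_cycle2_after_failure <- 0
  pt$sequence$start_cycle3_after_failure <- 0
  for (arm in ivf_strategies()) {
    out <- expected_program_outcomes(pt, arm)
    expect_identical(out$pregnancy, expected_fresh_pregnancy(pt, arm))
    expect_identical(out$expected_cost,
                     ivfcea:::fresh_cycle_values(pt, arm)$cost)
  }
})

test_that("program pregnancy is non-decreasing in each transition probability", {
  # the 13 stage/continuation probabilities (fresh-vs-frozen shares excluded:
  # they trade one cycle type for another, not failure for success)
  paths <- c(
    paste0("fresh.", c("oocyte_pickup", "usable_oocytes", "icsi_share",
                       "ivf_fertilization", "ivf_transfer", "ivf_pregnancy",
                       "icsi_fertilization", "icsi_transfer", "icsi_pregnancy")),
    "frozen.embryo_survival", "frozen.pregnancy_after_survival",
    "sequence.start_cycle2_after_failure", "sequence.start_cycle3_after_failure"
  )
  base <- midpoint_parameters(ivf_parameters())
  for (path in paths) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    for (arm in ivf_strategies()) {
      get_val <- function(pt) {
        if (parts[1] == "fresh") pt$fresh[[arm]][[parts[2]]] else pt[[parts[1]]][[parts[2]]]
      }
      set_val <- function(pt, v) {
        if (parts[1] == "fresh") pt$fresh[[arm]][[parts[2]]] <- v else pt[[parts[1]]][[parts[2]]] <- v
        pt
      }
      grid <- seq(0, 1, by = 0.25)
      preg <- vapply(grid, function(v) {
        expected_program_outcomes(set_val(base, v), arm)$pregnancy
      }, numeric(1))
      expect_true(all(diff(preg) >= -1e-12),
                  info = paste(path, arm))
    }
  }
})

test_that("expected cost is linear and non-decreasing in unit costs, and never affects pregnancy", {
  base <- midpoint_parameters(ivf_parameters())
  p0 <- expected_program_outcomes(base, "rfsh_myoins")
  for (item in c("ivf_lab", "freeze_and_thaw", "stim_rfsh_myoins")) {
    pt <- base
    pt$costs[[item]] <- pt$costs[[item]] + 50
    p1 <- expected_program_outcomes(pt, "rfsh_myoins")
    expect_identical(p1$pregnancy, p0$pregnancy)
    expect_gt(p1$expected_cost, p0$expected_cost)
  }
})

test_that("point validation rejects out-of-range values", {
  pt <- midpoint_parameters(ivf_parameters())
  pt$fresh$rfsh$ivf_pregnancy <- 1.2
  expect_error(expected_program_outcomes(pt, "rfsh"), "probability")
  pt <- midpoint_parameters(ivf_parameters())
  pt$costs$ivf_lab <- -3
  expect_error(expected_fresh_pregnancy(pt, "rfsh"), "negative cost")
})
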