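test_that("forced all-certain IVF path accrues the hand-summed item total", {
  params <- certain_success_midpoint_costs()
  set.seed(1)
  cyc <- simulate_fresh_cycle(params, "rfsh_myoins")
  expect_equal(cyc$terminal_stage, "pregnant")
  expect_true(cyc$pregnant)
  expect_equal(cyc$technique, "ivf")
  expect_equal(cyc$cost, FORCED_IVF_PATH_COST)
  expect_equal(sum(cyc$cost_items), cyc$cost)
})

test_that("forced pickup failure accrues only the fixed pre-pickup items", {
  params <- certain_success_midpoint_costs()
  params$fresh$rfsh_myoins$oocyte_pickup <- c(0, 0)
  set.seed(1)
  cyc <- simulate_fresh_cycle(params, "rfsh_myoins")
  expect_equal(cyc$terminal_stage, "pickup_failed")
  expect_false(cyc$pregnant)
  expect_equal(cyc$technique, "none")
  expect_equal(cyc$cost, FORCED_PREPICKUP_COST)
})

test_that("forced frozen-cycle paths cost thaw (+ catheter on survival)", {
  params <- certain_success_midpoint_costs()
  set.seed(1)
  cyc <- simulate_frozen_cycle(params)
  expect_equal(cyc$terminal_stage, "pregnant")
  expect_equal(cyc$cost, 325 + 150)
  params$frozen$embryo_survival <- c(0, 0)
  set.seed(1)
  cyc <- simulate_frozen_cycle(params)
  expect_equal(cyc$terminal_stage, "thaw_failed")
  expect_equal(cyc$cost, 325)
})

test_that("degenerate sequencing pins the number of cycles", {
  # no continuation and no pregnancies: exactly one failed cycle
  params <- degenerate_scenario("single_cycle_only")
  for (arm in ivf_strategies()) {
    params$fresh[[arm]]$ivf_pregnancy <- c(0, 0)
    params$fresh[[arm]]$icsi_pregnancy <- c(0, 0)
  }
  set.seed(2)
  out <- simulate_patient(params, "rfsh_myoins")
  expect_equal(out$cycles_used, 1L)
  expect_false(out$pregnant)

  # certain first-cycle success: one pregnant fresh cycle
  set.seed(3)
  out <- simulate_patient(degenerate_scenario("certain_success"), "rfsh")
  expect_equal(out$cycles_used, 1L)
  expect_true(out$pregnant)
  expect_equal(out$cycles[[1]]$kind, "fresh")
})

test_that("patient trajectories satisfy the program invariants", {
  scenarios <- c(list(ivf_parameters()), lapply(c(4, 5, 6), random_scenario))
  for (params in scenarios) {
    lo_fixed <- sum(
      params$costs$stim_rfsh_myoins[1], params$costs$other_hormones[1],
      params$costs$monitoring_ultrasounds[1], params$costs$consultations[1]
    )
    pats <- run_patients(params, "rfsh_myoins", n = 80, seed = 11)
    for (pat in pats) {
      expect_true(pat$cycles_used %in% 1:3)
      expect_equal(pat$cycles_used, length(pat$cycles))
      expect_equal(pat$cycles[[1]]$kind, "fresh")
      costs <- vapply(pat$cycles, `[[`, numeric(1), "cost")
      expect_equal(pat$total_cost, sum(costs))
      expect_gte(pat$total_cost, lo_fixed)
      pregs <- vapply(pat$cycles, `[[`, logical(1), "pregnant")
      expect_equal(pat$pregnant, pregs[length(pregs)])
      # pregnancy is absorbing: no cycle follows a pregnant one
      if (any(pregs)) expect_equal(which(pregs), length(pregs))
      for (cyc in pat$cycles) {
        expect_equal(cyc$cost, sum(cyc$cost_items))
        expect_equal(cyc$pregnant, cyc$terminal_stage == "pregnant")
        if (cyc$kind == "frozen") expect_equal(cyc$technique, "none")
      }
    }
  }
})

test_that("with degenerate ranges, realized (stage, cost) pairs match the tree enumeration", {
  params <- degenerate_at_midpoints(ivf_parameters())
  pt <- midpoint_parameters(params)

  # fresh cycle: every simulated pair must be an enumerated path, and with
  # enough draws every enumerated path is realized
  enum <- enum_fresh_paths(pt, "rfsh_myoins")
  enum_keys <- paste(enum$stage, round(enum$cost, 6))
  set.seed(19)
  sim_keys <- replicate(3000, {
    cyc <- simulate_fresh_cycle(params, "rfsh_myoins")
    paste(cyc$terminal_stage, round(cyc$cost, 6))
  })
  expect_true(all(sim_keys %in% enum_keys))
  expect_setequal(unique(sim_keys), enum_keys)

  # frozen cycle likewise
  enum_z <- enum_frozen_paths(pt)
  keys_z <- paste(enum_z$stage, round(enum_z$cost, 6))
  set.seed(20)
  sim_z <- replicate(800, {
    cyc <- simulate_frozen_cycle(params)
    paste(cyc$terminal_stage, round(cyc$cost, 6))
  })
  expect_true(all(sim_z %in% keys_z))
  expect_setequal(unique(sim_z), keys_z)

  # full program: every simulated (pregnant, total cost) pair is enumerated
  paths <- enum_program_paths(pt, "rfsh_myoins")
  prog_keys <- unique(paste(paths$pregnant, round(paths$cost, 6)))
  set.seed(21)
  for (pat in run_patients(params, "rfsh_myoins", n = 400, seed = 21)) {
    expect_true(paste(pat$pregnant, round(pat$total_cost, 6)) %in% prog_keys)
  }
})

test_that("strict embryo gating forbids frozen cycles without a fertilized embryo", {
  params <- ivf_parameters()
  for (arm in ivf_strategies()) {
    params$fresh[[arm]]$ivf_fertilization <- c(0, 0)
    params$fresh[[arm]]$icsi_fertilization <- c(0, 0)
  }
  params$sequence$start_cycle2_after_failure <- c(1, 1)
  params$sequence$start_cycle3_after_failure <- c(1, 1)
  params$sequence$fresh_share_cycle2 <- c(0, 0)  # always prefer frozen
  params$sequence$fresh_share_cycle3 <- c(0, 0)

  strict <- run_patients(params, "rfsh", n = 60, seed = 9,
                         mode = "strict_embryo_gating")
  kinds <- unlist(lapply(strict, function(p) {
    vapply(p$cycles, `[[`, character(1), "kind")
  }))
  expect_true(all(kinds == "fresh"))  # fallback to fresh in every slot

  faithful <- run_patients(params, "rfsh", n = 60, seed = 9,
                           mode = "table_faithful")
  kinds_f <- unlist(lapply(faithful, function(p) {
    vapply(p$cycles, `[[`, character(1), "kind")
  }))
  expect_true(any(kinds_f == "frozen"))
})

test_that("identical seeds reproduce identical patient sequences", {
  a <- run_patients(ivf_parameters(), "rfsh_myoins", n = 25, seed = 123)
  b <- run_patients(ivf_parameters(), "rfsh_myoins", n = 25, seed = 123)
  expect_identical(a, b)
})

test_that("invalid parameters are rejected before simulation", {
  bad <- ivf_parameters()
  bad$costs$ivf_lab <- c(-5, 10)
  expect_error(simulate_fresh_cycle(bad, "rfsh"), "invalid parameters")
  expect_error(simulate_patient(bad, "rfsh"), "invalid parameters")
})

test_that("patient trajectories export one audit row per cycle", {
  set.seed(31)
  pat <- simulate_patient(ivf_parameters(), "rfsh_myoins")
  df <- as.data.frame(pat)
  expect_equal(nrow(df), pat$cycles_used)
  expect_equal(df$cycle, seq_len(pat$cycles_used))
  expect_equal(sum(df$cost), pat$total_cost)
  expect_equal(df$kind[1], "fresh")
})
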