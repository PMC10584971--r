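# Flat exhaustive enumeration of the decision tree at a fixed parameter
# point. Deliberately independent of the package's closed-form recursion:
# every terminal path is listed with its probability and cost, and
# expectations are probability-weighted sums over paths.

enum_fresh_paths <- function(pt, strategy, ohss_prob = 0) {
  fp <- pt$fresh[[strategy]]
  cs <- pt$costs
  stim <- if (strategy == "rfsh_myoins") cs$stim_rfsh_myoins else cs$stim_rfsh
  c0 <- stim + cs$other_hormones + cs$monitoring_ultrasounds +
    cs$consultations + ohss_prob * cs$ohss_treatment
  rows <- list()
  add <- function(prob, cost, pregnant, fert, stage) {
    rows[[length(rows) + 1L]] <<- data.frame(
      prob = prob, cost = cost, pregnant = pregnant, fert = fert,
      stage = stage, stringsAsFactors = FALSE)
  }
  add(1 - fp$oocyte_pickup, c0, FALSE, FALSE, "pickup_failed")
  c1 <- c0 + cs$oocyte_pickup + cs$pickup_ultrasound
  add(fp$oocyte_pickup * (1 - fp$usable_oocytes), c1, FALSE, FALSE,
      "no_usable_oocytes")
  reach <- fp$oocyte_pickup * fp$usable_oocytes
  for (tech in c("ivf", "icsi")) {
    w <- if (tech == "icsi") fp$icsi_share else 1 - fp$icsi_share
    lab <- if (tech == "icsi") cs$icsi_procedure + cs$icsi_lab else cs$ivf_lab
    fert <- fp[[paste0(tech, "_fertilization")]]
    tr <- fp[[paste0(tech, "_transfer")]]
    pg <- fp[[paste0(tech, "_pregnancy")]]
    cath <- if (tech == "icsi") cs$icsi_et_catheter else cs$fresh_et_ivf_catheter
    c2 <- c1 + lab
    add(reach * w * (1 - fert), c2, FALSE, FALSE, "fertilization_failed")
    add(reach * w * fert * (1 - tr), c2, FALSE, TRUE, "transfer_not_reached")
    add(reach * w * fert * tr * (1 - pg), c2 + cath, FALSE, TRUE,
        "transfer_failed")
    add(reach * w * fert * tr * pg, c2 + cath, TRUE, TRUE, "pregnant")
  }
  do.call(rbind, rows)
}

enum_frozen_paths <- function(pt) {
  fz <- pt$frozen
  cs <- pt$costs
  s <- fz$embryo_survival
  z <- fz$pregnancy_after_survival
  data.frame(
    prob = c(1 - s, s * (1 - z), s * z),
    cost = c(cs$freeze_and_thaw,
             cs$freeze_and_thaw + cs$frozen_et_catheter,
             cs$freeze_and_thaw + cs$frozen_et_catheter),
    pregnant = c(FALSE, FALSE, TRUE),
    fert = FALSE,
    stage = c("thaw_failed", "transfer_failed", "pregnant"),
    stringsAsFactors = FALSE
  )
}

# all terminal paths of the up-to-3-cycle program (table_faithful mode);
# n_fresh counts fresh cycles for the cost-linearity checks
enum_program_paths <- function(pt, strategy, ohss_prob = 0) {
  fr <- enum_fresh_paths(pt, strategy, ohss_prob)
  fz <- enum_frozen_paths(pt)
  sq <- pt$sequence
  stage_options <- function(start, share) {
    opts <- list(list(prob = 1 - start, cost = 0, pregnant = FALSE,
                      cycles = 0L, fresh = 0L))
    for (i in seq_len(nrow(fr))) {
      opts[[length(opts) + 1L]] <- list(prob = start * share * fr$prob[i],
                                        cost = fr$cost[i],
                                        pregnant = fr$pregnant[i],
                                        cycles = 1L, fresh = 1L)
    }
    for (i in seq_len(nrow(fz))) {
      opts[[length(opts) + 1L]] <- list(prob = start * (1 - share) * fz$prob[i],
                                        cost = fz$cost[i],
                                        pregnant = fz$pregnant[i],
                                        cycles = 1L, fresh = 0L)
    }
    opts
  }
  o2 <- stage_options(sq$start_cycle2_after_failure, sq$fresh_share_cycle2)
  o3 <- stage_options(sq$start_cycle3_after_failure, sq$fresh_share_cycle3)
  rows <- list()
  add <- function(prob, cost, pregnant, cycles, fresh) {
    rows[[length(rows) + 1L]] <<- data.frame(
      prob = prob, cost = cost, pregnant = pregnant,
      cycles = cycles, n_fresh = fresh)
  }
  for (i in seq_len(nrow(fr))) {
    p1 <- fr$prob[i]; c1 <- fr$cost[i]
    if (fr$pregnant[i]) { add(p1, c1, TRUE, 1L, 1L); next }
    for (a in o2) {
      if (a$pregnant) {
        add(p1 * a$prob, c1 + a$cost, TRUE, 1L + a$cycles, 1L + a$fresh)
        next
      }
      for (b in o3) {
        add(p1 * a$prob * b$prob, c1 + a$cost + b$cost, b$pregnant,
            1L + a$cycles + b$cycles, 1L + a$fresh + b$fresh)
      }
    }
  }
  do.call(rbind, rows)
}

enum_program_expectations <- function(pt, strategy, ohss_prob = 0) {
  paths <- enum_program_paths(pt, strategy, ohss_prob)
  list(
    total_prob = sum(paths$prob),
    pregnancy = sum(paths$prob * paths$pregnant),
    expected_cost = sum(paths$prob * paths$cost),
    expected_cycles = sum(paths$prob * paths$cycles),
    expected_fresh_cycles = sum(paths$prob * paths$n_fresh)
  )
}
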