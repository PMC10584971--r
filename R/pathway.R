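# Per-patient pathway engine. One fresh cycle walks the chain
# stimulation -> oocyte pickup -> usable oocytes -> IVF/ICSI assignment ->
# fertilization -> embryo transfer -> ongoing pregnancy, accruing unit costs
# as each stage is reached. A frozen cycle is thaw -> survival -> transfer ->
# pregnancy. Every probability and every unit cost is redrawn uniformly from
# its range at every use (probabilistic sensitivity analysis semantics).

# one uniform draw from a range c(lo, hi)
draw1 <- function(r) stats::runif(1L, r[[1L]], r[[2L]])
# Bernoulli event whose probability is itself drawn from a range
event1 <- function(r) stats::runif(1L) < draw1(r)

stim_item_for <- function(strategy) {
  if (strategy == "rfsh_myoins") "stim_rfsh_myoins" else "stim_rfsh"
}

new_cycle <- function(kind, technique, terminal_stage, items) {
  structure(list(
    kind = kind,
    technique = technique,
    terminal_stage = terminal_stage,
    pregnant = terminal_stage == "pregnant",
    cost = sum(items),
    cost_items = items
  ), class = "ivf_cycle")
}

# did a fresh cycle produce at least one fertilized embryo?
cycle_fertilized <- function(cycle) {
  cycle$kind == "fresh" &&
    cycle$terminal_stage %in% c("transfer_not_reached", "transfer_failed", "pregnant")
}

#' Simulate one fresh IVF cycle
#'
#' Walks a single patient through the fresh-cycle pathway under one
#' stimulation strategy: fixed pre-pickup costs (stimulation drug, other
#' hormones, monitoring ultrasounds, consultations), then the chain of
#' stage events — oocyte pickup, usable oocytes, IVF/ICSI technique
#' assignment, fertilization, embryo transfer, ongoing pregnancy — with
#' stage-conditional cost accrual. Uses the current R random stream; seed
#' with [set.seed()] for reproducibility.
#'
#' @param params An `ivf_parameters` object.
#' @param strategy `"rfsh_myoins"` or `"rfsh"`.
#' @param ohss_prob Probability that an OHSS treatment cost is incurred in
#'   this cycle (default 0: the OHSS item is not accrued).
#' @return An `ivf_cycle` object: `kind` (`"fresh"`), `technique` (`"ivf"`,
#'   `"icsi"`, or `"none"` if the cycle ended before technique assignment),
#'   `terminal_stage` (one of `pickup_failed`, `no_usable_oocytes`,
#'   `fertilization_failed`, `transfer_not_reached`, `transfer_failed`,
#'   `pregnant`), `pregnant`, `cost` (euros), and the itemized `cost_items`.
#' @examples
#' set.seed(1)
#' simulate_fresh_cycle(ivf_parameters(), "rfsh_myoins")
#' @export
simulate_fresh_cycle <- function(params, strategy = ivf_strategies(),
                                 ohss_prob = 0) {
  strategy <- match.arg(strategy)
  assert_valid_parameters(params)
  fp <- params$fresh[[strategy]]
  cs <- params$costs
  items <- c(
    stats::setNames(draw1(cs[[stim_item_for(strategy)]]), stim_item_for(strategy)),
    other_hormones = draw1(cs$other_hormones),
    monitoring_ultrasounds = draw1(cs$monitoring_ultrasounds),
    consultations = draw1(cs$consultations)
  )
  if (ohss_prob > 0 && stats::runif(1L) < ohss_prob) {
    items["ohss_treatment"] <- draw1(cs$ohss_treatment)
  }
  if (!event1(fp$oocyte_pickup)) {
    return(new_cycle("fresh", "none", "pickup_failed", items))
  }
  items["oocyte_pickup"] <- draw1(cs$oocyte_pickup)
  items["pickup_ultrasound"] <- draw1(cs$pickup_ultrasound)
  if (!event1(fp$usable_oocytes)) {
    return(new_cycle("fresh", "none", "no_usable_oocytes", items))
  }
  icsi <- event1(fp$icsi_share)
  technique <- if (icsi) "icsi" else "ivf"
  if (icsi) {
    items["icsi_procedure"] <- draw1(cs$icsi_procedure)
    items["icsi_lab"] <- draw1(cs$icsi_lab)
  } else {
    items["ivf_lab"] <- draw1(cs$ivf_lab)
  }
  fert <- if (icsi) fp$icsi_fertilization else fp$ivf_fertilization
  if (!event1(fert)) {
    return(new_cycle("fresh", technique, "fertilization_failed", items))
  }
  transfer <- if (icsi) fp$icsi_transfer else fp$ivf_transfer
  if (!event1(transfer)) {
    return(new_cycle("fresh", technique, "transfer_not_reached", items))
  }
  cath <- if (icsi) "icsi_et_catheter" else "fresh_et_ivf_catheter"
  items[cath] <- draw1(cs[[cath]])
  preg <- if (icsi) fp$icsi_pregnancy else fp$ivf_pregnancy
  stage <- if (event1(preg)) "pregnant" else "transfer_failed"
  new_cycle("fresh", technique, stage, items)
}

#' Simulate one frozen embryo-transfer cycle
#'
#' Thaws a cryopreserved embryo (accruing the freeze-and-thaw cost), tests
#' embryo survival, and on survival accrues the transfer catheter cost and
#' runs the ongoing-pregnancy event.
#'
#' @inheritParams simulate_fresh_cycle
#' @return An `ivf_cycle` object with `kind = "frozen"`, `technique = "none"`,
#'   and `terminal_stage` one of `thaw_failed`, `transfer_failed`, `pregnant`.
#' @export
simulate_frozen_cycle <- function(params) {
  assert_valid_parameters(params)
  fz <- params$frozen
  cs <- params$costs
  items <- c(freeze_and_thaw = draw1(cs$freeze_and_thaw))
  if (!event1(fz$embryo_survival)) {
    return(new_cycle("frozen", "none", "thaw_failed", items))
  }
  items["frozen_et_catheter"] <- draw1(cs$frozen_et_catheter)
  stage <- if (event1(fz$pregnancy_after_survival)) "pregnant" else "transfer_failed"
  new_cycle("frozen", "none", stage, items)
}

#' Simulate one patient's full treatment program
#'
#' Runs up to three treatment cycles. The first cycle is always fresh. After
#' a failed first cycle the patient starts a second cycle with probability
#' drawn from `start_cycle2_after_failure`, fresh with probability from
#' `fresh_share_cycle2`, otherwise frozen. If the patient is still not
#' pregnant after the second-cycle stage — whether the second cycle was run
#' or declined — a third cycle is started with probability from
#' `start_cycle3_after_failure` (fresh share `fresh_share_cycle3`). The
#' program stops at the first pregnancy.
#'
#' In mode `"strict_embryo_gating"` a frozen cycle is only available if some
#' earlier fresh cycle reached successful fertilization (so a cryopreserved
#' embryo can exist); otherwise that cycle falls back to fresh. The default
#' `"table_faithful"` mode makes frozen cycles available unconditionally at
#' the tabulated shares.
#'
#' @inheritParams simulate_fresh_cycle
#' @param mode `"table_faithful"` (default) or `"strict_embryo_gating"`.
#' @return An `ivf_patient` object: `strategy`, `cycles` (list of 1--3
#'   [`ivf_cycle`][simulate_fresh_cycle] realizations), `pregnant`,
#'   `total_cost` (euros), `cycles_used`.
#' @examples
#' set.seed(42)
#' simulate_patient(ivf_parameters(), "rfsh_myoins")
#' @export
simulate_patient <- function(params, strategy = ivf_strategies(),
                             mode = c("table_faithful", "strict_embryo_gating"),
                             ohss_prob = 0) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  assert_valid_parameters(params)
  sq <- params$sequence
  strict <- mode == "strict_embryo_gating"

  cycles <- list(simulate_fresh_cycle(params, strategy, ohss_prob))
  had_fert <- cycle_fertilized(cycles[[1L]])

  next_cycle <- function(share_range) {
    want_fresh <- event1(share_range)
    if (!want_fresh && strict && !had_fert) want_fresh <- TRUE
    if (want_fresh) {
      simulate_fresh_cycle(params, strategy, ohss_prob)
    } else {
      simulate_frozen_cycle(params)
    }
  }

  if (!cycles[[length(cycles)]]$pregnant && event1(sq$start_cycle2_after_failure)) {
    cyc <- next_cycle(sq$fresh_share_cycle2)
    cycles <- c(cycles, list(cyc))
    had_fert <- had_fert || cycle_fertilized(cyc)
  }
  if (!cycles[[length(cycles)]]$pregnant && event1(sq$start_cycle3_after_failure)) {
    cyc <- next_cycle(sq$fresh_share_cycle3)
    cycles <- c(cycles, list(cyc))
  }

  structure(list(
    strategy = strategy,
    cycles = cycles,
    pregnant = cycles[[length(cycles)]]$pregnant,
    total_cost = sum(vapply(cycles, `[[`, numeric(1L), "cost")),
    cycles_used = length(cycles)
  ), class = "ivf_patient")
}

#' Simulate a list of patients on a seeded stream
#'
#' Convenience wrapper producing `n` independent [simulate_patient()]
#' trajectories from a single seeded random stream, for audit and export.
#' For large cohorts use [run_cohort()], which is vectorized.
#'
#' @inheritParams simulate_patient
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return A list of `n` `ivf_patient` objects.
#' @export
run_patients <- function(params, strategy = ivf_strategies(), n, seed = 1L,
                         mode = c("table_faithful", "strict_embryo_gating"),
                         ohss_prob = 0) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  assert_valid_parameters(params)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    simulate_patient(params, strategy, mode, ohss_prob)
  })
}

#' @export
print.ivf_cycle <- function(x, ...) {
  cat(sprintf("<%s cycle> technique=%s stage=%s cost=%.2f EUR\n",
              x$kind, x$technique, x$terminal_stage, x$cost))
  invisible(x)
}

#' @export
print.ivf_patient <- function(x, ...) {
  cat(sprintf("<ivf_patient> strategy=%s cycles=%d pregnant=%s total_cost=%.2f EUR\n",
              x$strategy, x$cycles_used, x$pregnant, x$total_cost))
  for (i in seq_along(x$cycles)) {
    cat(sprintf("  cycle %d: ", i)); print(x$cycles[[i]])
  }
  invisible(x)
}

#' One row per cycle of a simulated patient
#'
#' @param x An `ivf_patient` object.
#' @param row.names,optional,... Ignored.
#' @return Data frame with columns `strategy`, `cycle`, `kind`, `technique`,
#'   `terminal_stage`, `pregnant`, `cost` — suitable for rbinding across
#'   patients and writing to CSV for audit.
#' @export
as.data.frame.ivf_patient <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$cycles), function(i) {
    cyc <- x$cycles[[i]]
    data.frame(
      strategy = x$strategy, cycle = i, kind = cyc$kind,
      technique = cyc$technique, terminal_stage = cyc$terminal_stage,
      pregnant = cyc$pregnant, cost = cyc$cost, stringsAsFactors = FALSE
    )
  }))
}
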