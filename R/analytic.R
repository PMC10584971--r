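# Closed-form expected-value evaluation of the treatment-program decision
# tree at a fixed parameter point. Because every probability and cost is
# redrawn independently at each use, every program-level expectation is
# multilinear in the parameters, so evaluating the tree at range midpoints
# gives the exact mean of the stochastic simulation.

#' Collapse parameter ranges to their midpoints
#'
#' Replaces every uniform range `[lo, hi]` by its mean `(lo + hi) / 2`.
#' Since each parameter is drawn uniformly and independently at every use,
#' the midpoint point evaluation of the decision tree equals the exact
#' expectation of the simulation.
#'
#' @param params An `ivf_parameters` object.
#' @return An `ivf_point` object with the same nesting but scalar values.
#' @examples
#' midpoint_parameters(ivf_parameters())$fresh$rfsh_myoins$oocyte_pickup # 0.75
#' @export
midpoint_parameters <- function(params) {
  assert_valid_parameters(params)
  structure(rapply(unclass(params), function(r) mean(r), how = "replace"),
            class = "ivf_point")
}

# accept either a full parameter set (collapsed to midpoints) or a point
as_point <- function(x) {
  if (inherits(x, "ivf_point")) return(x)
  if (inherits(x, "ivf_parameters")) return(midpoint_parameters(x))
  stop("expected an ivf_parameters or ivf_point object", call. = FALSE)
}

assert_valid_point <- function(pt) {
  probs <- c(unlist(pt$fresh), unlist(pt$frozen), unlist(pt$sequence))
  if (any(probs < 0 | probs > 1)) {
    stop("point parameters contain a probability outside [0,1]", call. = FALSE)
  }
  if (any(unlist(pt$costs) < 0)) {
    stop("point parameters contain a negative cost", call. = FALSE)
  }
  invisible(pt)
}

# expected pregnancy probability, expected cost, and fertilization-reach
# probability for one fresh cycle at a fixed point
fresh_cycle_values <- function(pt, strategy, ohss_prob = 0) {
  fp <- pt$fresh[[strategy]]
  cs <- pt$costs
  w <- fp$icsi_share
  reach_tech <- fp$oocyte_pickup * fp$usable_oocytes
  branch <- function(fert, transfer, preg) c(f = fert, t = fert * transfer,
                                             p = fert * transfer * preg)
  ivf <- branch(fp$ivf_fertilization, fp$ivf_transfer, fp$ivf_pregnancy)
  icsi <- branch(fp$icsi_fertilization, fp$icsi_transfer, fp$icsi_pregnancy)
  pregnancy <- reach_tech * ((1 - w) * ivf[["p"]] + w * icsi[["p"]])
  fert_prob <- reach_tech * ((1 - w) * ivf[["f"]] + w * icsi[["f"]])
  cost <- cs[[stim_item_for(strategy)]] + cs$other_hormones +
    cs$monitoring_ultrasounds + cs$consultations +
    ohss_prob * cs$ohss_treatment +
    fp$oocyte_pickup * (cs$oocyte_pickup + cs$pickup_ultrasound) +
    reach_tech * ((1 - w) * cs$ivf_lab + w * (cs$icsi_procedure + cs$icsi_lab)) +
    reach_tech * ((1 - w) * ivf[["t"]] * cs$fresh_et_ivf_catheter +
                    w * icsi[["t"]] * cs$icsi_et_catheter)
  list(pregnancy = pregnancy, cost = cost, fert_prob = fert_prob)
}

frozen_cycle_values <- function(pt) {
  fz <- pt$frozen
  cs <- pt$costs
  list(
    pregnancy = fz$embryo_survival * fz$pregnancy_after_survival,
    cost = cs$freeze_and_thaw + fz$embryo_survival * cs$frozen_et_catheter
  )
}

#' Expected fresh-cycle pregnancy probability at a parameter point
#'
#' Closed form over the fresh-cycle branch structure:
#' `pickup * usable * ((1 - icsi_share) * ivf_fert * ivf_transfer * ivf_preg
#' + icsi_share * icsi_fert * icsi_transfer * icsi_preg)`.
#'
#' @param point An `ivf_point` (or an `ivf_parameters` object, which is
#'   collapsed to midpoints first).
#' @param strategy `"rfsh_myoins"` or `"rfsh"`.
#' @return The ongoing-pregnancy probability of a single fresh cycle.
#' @examples
#' expected_fresh_pregnancy(ivf_parameters(), "rfsh_myoins") # ~0.128
#' @export
expected_fresh_pregnancy <- function(point, strategy = ivf_strategies()) {
  strategy <- match.arg(strategy)
  pt <- as_point(point)
  assert_valid_point(pt)
  fresh_cycle_values(pt, strategy)$pregnancy
}

#' Exact expected outcomes of the full multi-cycle program
#'
#' Evaluates the three-cycle decision tree in closed form at a fixed
#' parameter point: cycle 1 fresh; a failed patient starts cycle 2 with the
#' continuation probability (fresh/frozen per the tabulated share); a patient
#' not pregnant after the cycle-2 stage (run or declined) is considered for
#' cycle 3 likewise. Expected cost accrues each unit cost weighted by the
#' probability its stage is reached. Because the simulation redraws every
#' parameter at every use, this multilinear tree value is the exact mean of
#' [run_cohort()] under `mode = "table_faithful"`.
#'
#' @inheritParams expected_fresh_pregnancy
#' @param ohss_prob Per-fresh-cycle probability of the OHSS cost item
#'   (default 0, matching the default cost model).
#' @return A list: `pregnancy` (program ongoing-pregnancy probability),
#'   `expected_cost` (euros), `cost_per_pregnancy`, `expected_cycles`, and
#'   `expected_fresh_cycles`.
#' @examples
#' expected_program_outcomes(ivf_parameters(), "rfsh_myoins")
#' @export
expected_program_outcomes <- function(point, strategy = ivf_strategies(),
                                      ohss_prob = 0) {
  strategy <- match.arg(strategy)
  pt <- as_point(point)
  assert_valid_point(pt)
  fr <- fresh_cycle_values(pt, strategy, ohss_prob)
  fz <- frozen_cycle_values(pt)
  sq <- pt$sequence
  p1 <- fr$pregnancy; E1 <- fr$cost
  pz <- fz$pregnancy; Ez <- fz$cost
  c2 <- sq$start_cycle2_after_failure; s2 <- sq$fresh_share_cycle2
  c3 <- sq$start_cycle3_after_failure; s3 <- sq$fresh_share_cycle3
  p2 <- s2 * p1 + (1 - s2) * pz
  E2 <- s2 * E1 + (1 - s2) * Ez
  p3 <- s3 * p1 + (1 - s3) * pz
  E3 <- s3 * E1 + (1 - s3) * Ez
  attempt2 <- (1 - p1) * c2
  not_pregnant_after2 <- (1 - p1) * (c2 * (1 - p2) + (1 - c2))
  attempt3 <- not_pregnant_after2 * c3
  pregnancy <- p1 + attempt2 * p2 + attempt3 * p3
  cost <- E1 + attempt2 * E2 + attempt3 * E3
  list(
    pregnancy = pregnancy,
    expected_cost = cost,
    cost_per_pregnancy = if (pregnancy > 0) cost / pregnancy else NA_real_,
    expected_cycles = 1 + attempt2 + attempt3,
    expected_fresh_cycles = 1 + attempt2 * s2 + attempt3 * s3
  )
}

#' Analytic outcome table for both strategies
#'
#' @param params An `ivf_parameters` object (evaluated at range midpoints)
#'   or an `ivf_point`.
#' @param ohss_prob Per-fresh-cycle OHSS cost probability (default 0).
#' @return A data frame with one row per strategy: `strategy`, `pregnancy`,
#'   `expected_cost`, `cost_per_pregnancy`, `expected_cycles`.
#' @examples
#' analytic_outcomes(ivf_parameters())
#' @export
analytic_outcomes <- function(params, ohss_prob = 0) {
  pt <- as_point(params)
  do.call(rbind, lapply(ivf_strategies(), function(arm) {
    o <- expected_program_outcomes(pt, arm, ohss_prob)
    data.frame(
      strategy = arm,
      pregnancy = o$pregnancy,
      expected_cost = o$expected_cost,
      cost_per_pregnancy = o$cost_per_pregnancy,
      expected_cycles = o$expected_cycles,
      stringsAsFactors = FALSE
    )
  }))
}
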