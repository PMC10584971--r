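# Cohort-level Monte Carlo. The engine is a vectorized implementation of the
# same decision tree that simulate_patient() walks one patient at a time:
# all stage probabilities, event uniforms and unit costs are drawn as
# length-m vectors, and logical masks carry each patient through the chain.

draw_m <- function(m, r) stats::runif(m, r[[1L]], r[[2L]])
event_m <- function(m, r) stats::runif(m) < draw_m(m, r)

# vectorized fresh cycle for m patients; returns pregnant / fert / cost
sim_fresh_vec <- function(m, params, strategy, ohss_prob = 0) {
  if (m == 0L) {
    return(list(pregnant = logical(0), fert = logical(0), cost = numeric(0)))
  }
  fp <- params$fresh[[strategy]]
  cs <- params$costs
  cost <- draw_m(m, cs[[stim_item_for(strategy)]]) +
    draw_m(m, cs$other_hormones) +
    draw_m(m, cs$monitoring_ultrasounds) +
    draw_m(m, cs$consultations)
  if (ohss_prob > 0) {
    cost <- cost + (stats::runif(m) < ohss_prob) * draw_m(m, cs$ohss_treatment)
  }
  ok_pickup <- event_m(m, fp$oocyte_pickup)
  cost <- cost + ok_pickup * (draw_m(m, cs$oocyte_pickup) +
                                draw_m(m, cs$pickup_ultrasound))
  ok_usable <- ok_pickup & event_m(m, fp$usable_oocytes)
  icsi <- event_m(m, fp$icsi_share)
  lab <- ifelse(icsi,
                draw_m(m, cs$icsi_procedure) + draw_m(m, cs$icsi_lab),
                draw_m(m, cs$ivf_lab))
  cost <- cost + ok_usable * lab
  p_fert <- ifelse(icsi, draw_m(m, fp$icsi_fertilization),
                   draw_m(m, fp$ivf_fertilization))
  ok_fert <- ok_usable & (stats::runif(m) < p_fert)
  p_transfer <- ifelse(icsi, draw_m(m, fp$icsi_transfer),
                       draw_m(m, fp$ivf_transfer))
  ok_transfer <- ok_fert & (stats::runif(m) < p_transfer)
  cath <- ifelse(icsi, draw_m(m, cs$icsi_et_catheter),
                 draw_m(m, cs$fresh_et_ivf_catheter))
  cost <- cost + ok_transfer * cath
  p_preg <- ifelse(icsi, draw_m(m, fp$icsi_pregnancy),
                   draw_m(m, fp$ivf_pregnancy))
  pregnant <- ok_transfer & (stats::runif(m) < p_preg)
  list(pregnant = pregnant, fert = ok_fert, cost = cost)
}

sim_frozen_vec <- function(m, params) {
  if (m == 0L) return(list(pregnant = logical(0), cost = numeric(0)))
  fz <- params$frozen
  cs <- params$costs
  cost <- draw_m(m, cs$freeze_and_thaw)
  survived <- event_m(m, fz$embryo_survival)
  cost <- cost + survived * draw_m(m, cs$frozen_et_catheter)
  pregnant <- survived & event_m(m, fz$pregnancy_after_survival)
  list(pregnant = pregnant, cost = cost)
}

#' Simulate a cohort of patients under one strategy
#'
#' Runs `n` independent patient trajectories through the up-to-three-cycle
#' program (see [simulate_patient()] for the pathway rules) on a single
#' seeded random stream, vectorized over patients. Results are reproducible:
#' the same `(params, strategy, n, seed, mode, ohss_prob)` always yields the
#' identical cohort.
#'
#' @inheritParams simulate_patient
#' @param n Number of simulated patients (default 100000).
#' @param seed Integer seed for the random stream.
#' @param subcohort_size Size of the disjoint sub-cohorts over which the
#'   pregnancy-rate dispersion is later computed (default 150); stored on
#'   the cohort and used by [summary.ivf_cohort()].
#' @return An `ivf_cohort` object holding the per-patient records
#'   (`$patients`: data frame with `cost`, `pregnant`, `cycles_used`) and the
#'   run metadata.
#' @examples
#' co <- run_cohort(ivf_parameters(), "rfsh_myoins", n = 2000, seed = 7)
#' summary(co)
#' @export
run_cohort <- function(params, strategy = ivf_strategies(), n = 100000L,
                       seed = 1L,
                       mode = c("table_faithful", "strict_embryo_gating"),
                       ohss_prob = 0, subcohort_size = 150L) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  assert_valid_parameters(params)
  stopifnot(n >= 1L, ohss_prob >= 0, ohss_prob <= 1, subcohort_size >= 1L)
  n <- as.integer(n)
  strict <- mode == "strict_embryo_gating"
  sq <- params$sequence
  set.seed(seed)

  c1 <- sim_fresh_vec(n, params, strategy, ohss_prob)
  pregnant <- c1$pregnant
  cost <- c1$cost
  had_fert <- c1$fert
  cycles <- rep(1L, n)

  run_stage <- function(start_range, share_range) {
    attempt <- !pregnant & event_m(n, start_range)
    want_fresh <- event_m(n, share_range)
    frozen_ok <- if (strict) had_fert else rep(TRUE, n)
    do_frozen <- attempt & !want_fresh & frozen_ok
    do_fresh <- attempt & !do_frozen
    if (any(do_fresh)) {
      r <- sim_fresh_vec(sum(do_fresh), params, strategy, ohss_prob)
      pregnant[do_fresh] <<- r$pregnant
      cost[do_fresh] <<- cost[do_fresh] + r$cost
      had_fert[do_fresh] <<- had_fert[do_fresh] | r$fert
    }
    if (any(do_frozen)) {
      r <- sim_frozen_vec(sum(do_frozen), params)
      pregnant[do_frozen] <<- r$pregnant
      cost[do_frozen] <<- cost[do_frozen] + r$cost
    }
    cycles[attempt] <<- cycles[attempt] + 1L
    invisible(NULL)
  }

  run_stage(sq$start_cycle2_after_failure, sq$fresh_share_cycle2)
  run_stage(sq$start_cycle3_after_failure, sq$fresh_share_cycle3)

  structure(list(
    strategy = strategy, n = n, seed = as.integer(seed), mode = mode,
    ohss_prob = ohss_prob, subcohort_size = as.integer(subcohort_size),
    patients = data.frame(cost = cost, pregnant = pregnant,
                          cycles_used = cycles)
  ), class = "ivf_cohort")
}

#' @export
print.ivf_cohort <- function(x, ...) {
  cat(sprintf("<ivf_cohort> strategy=%s n=%d seed=%d mode=%s\n",
              x$strategy, x$n, x$seed, x$mode))
  print(summary(x))
  invisible(x)
}

#' Summarize a simulated cohort
#'
#' Computes the three headline outcomes with their dispersions: mean total
#' cost per patient (SD across patients), ongoing-pregnancy rate (SD across
#' disjoint sub-cohorts of `subcohort_size` patients; a trailing partial
#' sub-cohort is dropped), and cost per pregnancy, defined as
#' `mean_cost / pregnancy_rate` on the unrounded rate, with dispersion
#' `sd_cost / pregnancy_rate`. When no patient is pregnant the cost per
#' pregnancy is reported as `NA` (undefined), not infinite.
#'
#' @param object An `ivf_cohort` from [run_cohort()].
#' @param subcohort_size Override of the sub-cohort size stored on the cohort.
#' @param ... Ignored.
#' @return A `summary.ivf_cohort` list: `strategy`, `n`, `mean_cost`,
#'   `sd_cost`, `pregnancy_rate`, `sd_rate`, `cost_per_pregnancy`,
#'   `sd_cost_per_pregnancy`, `cycles_hist` (counts of patients using 1, 2,
#'   3 cycles), `subcohort_size`.
#' @export
summary.ivf_cohort <- function(object, subcohort_size = object$subcohort_size,
                               ...) {
  p <- object$patients
  n <- nrow(p)
  mean_cost <- mean(p$cost)
  sd_cost <- if (n > 1L) stats::sd(p$cost) else NA_real_
  rate <- mean(p$pregnant)
  k <- n %/% subcohort_size
  sd_rate <- if (k >= 2L) {
    idx <- seq_len(k * subcohort_size)
    grp <- rep(seq_len(k), each = subcohort_size)
    stats::sd(tapply(p$pregnant[idx], grp, mean))
  } else NA_real_
  cpp <- if (rate > 0) mean_cost / rate else NA_real_
  sd_cpp <- if (rate > 0 && !is.na(sd_cost)) sd_cost / rate else NA_real_
  structure(list(
    strategy = object$strategy, n = n,
    mean_cost = mean_cost, sd_cost = sd_cost,
    pregnancy_rate = rate, sd_rate = sd_rate,
    cost_per_pregnancy = cpp, sd_cost_per_pregnancy = sd_cpp,
    cycles_hist = tabulate(p$cycles_used, nbins = 3L),
    subcohort_size = as.integer(subcohort_size)
  ), class = "summary.ivf_cohort")
}

#' @export
print.summary.ivf_cohort <- function(x, ...) {
  fmt_sd <- function(s) if (is.na(s)) "NA (undefined)" else sprintf("%.0f", s)
  cat(sprintf("Strategy %-12s (n = %d patients)\n", x$strategy, x$n))
  cat(sprintf("  mean cost per patient : EUR %5.0f +/- %s\n",
              x$mean_cost, fmt_sd(x$sd_cost)))
  cat(sprintf("  ongoing-pregnancy rate: %.3f +/- %s (sub-cohorts of %d)\n",
              x$pregnancy_rate,
              if (is.na(x$sd_rate)) "NA (undefined)" else sprintf("%.3f", x$sd_rate),
              x$subcohort_size))
  if (is.na(x$cost_per_pregnancy)) {
    cat("  cost per pregnancy    : undefined (no pregnancies)\n")
  } else {
    cat(sprintf("  cost per pregnancy    : EUR %5.0f +/- %s\n",
                x$cost_per_pregnancy, fmt_sd(x$sd_cost_per_pregnancy)))
  }
  cat(sprintf("  cycles used 1/2/3     : %s\n",
              paste(x$cycles_hist, collapse = " / ")))
  invisible(x)
}

#' Compare two simulated cohorts
#'
#' Between-strategy contrasts of the headline outcomes (deltas are `a - b`),
#' with large-sample tests: a two-sample unequal-variance z test on
#' per-patient costs and a pooled two-proportion z test on pregnancy. The
#' dominance verdict calls `a` (or `b`) dominant when it is simultaneously
#' cheaper and more effective; anything else — including exact ties — is a
#' trade-off.
#'
#' @param a,b `ivf_cohort` objects (typically one per strategy, equal `n`).
#' @return An `ivf_comparison` list: the two strategy labels, `delta_cost`,
#'   `delta_rate`, `delta_cost_per_pregnancy`, `z_cost`, `p_cost`, `z_rate`,
#'   `p_rate`, and `verdict` (`"a_dominates"`, `"b_dominates"`,
#'   `"tradeoff"`).
#' @export
compare_strategies <- function(a, b) {
  stopifnot(inherits(a, "ivf_cohort"), inherits(b, "ivf_cohort"))
  sa <- summary(a); sb <- summary(b)
  na <- sa$n; nb <- sb$n
  delta_cost <- sa$mean_cost - sb$mean_cost
  delta_rate <- sa$pregnancy_rate - sb$pregnancy_rate
  delta_cpp <- sa$cost_per_pregnancy - sb$cost_per_pregnancy
  se_cost <- sqrt(stats::var(a$patients$cost) / na +
                    stats::var(b$patients$cost) / nb)
  # single-patient cohorts (or zero pooled variance) leave the z tests
  # undefined; report NA rather than a fabricated statistic
  z_cost <- if (is.finite(se_cost) && se_cost > 0) delta_cost / se_cost else NA_real_
  xa <- sum(a$patients$pregnant); xb <- sum(b$patients$pregnant)
  pool <- (xa + xb) / (na + nb)
  se_rate <- sqrt(pool * (1 - pool) * (1 / na + 1 / nb))
  z_rate <- if (is.finite(se_rate) && se_rate > 0) delta_rate / se_rate else NA_real_
  verdict <- if (delta_cost < 0 && delta_rate > 0) {
    "a_dominates"
  } else if (delta_cost > 0 && delta_rate < 0) {
    "b_dominates"
  } else {
    "tradeoff"
  }
  structure(list(
    strategy_a = a$strategy, strategy_b = b$strategy,
    delta_cost = delta_cost, delta_rate = delta_rate,
    delta_cost_per_pregnancy = delta_cpp,
    z_cost = z_cost,
    p_cost = if (is.na(z_cost)) NA_real_ else 2 * stats::pnorm(-abs(z_cost)),
    z_rate = z_rate,
    p_rate = if (is.na(z_rate)) NA_real_ else 2 * stats::pnorm(-abs(z_rate)),
    verdict = verdict
  ), class = "ivf_comparison")
}

# display convention for very small p-values
format_pval <- function(p) {
  if (is.na(p)) "undefined" else if (p < 1e-4) "< 0.0001" else sprintf("= %.4f", p)
}

#' @export
print.ivf_comparison <- function(x, ...) {
  cat(sprintf("Comparison: %s (a) vs %s (b)\n", x$strategy_a, x$strategy_b))
  cat(sprintf("  delta mean cost        : EUR %+.0f  (z = %.1f, p %s)\n",
              x$delta_cost, x$z_cost, format_pval(x$p_cost)))
  cat(sprintf("  delta pregnancy rate   : %+.3f   (z = %.1f, p %s)\n",
              x$delta_rate, x$z_rate, format_pval(x$p_rate)))
  cat(sprintf("  delta cost/pregnancy   : EUR %+.0f\n",
              x$delta_cost_per_pregnancy))
  verdict <- switch(x$verdict,
    a_dominates = sprintf("%s dominates (cheaper and more effective)", x$strategy_a),
    b_dominates = sprintf("%s dominates (cheaper and more effective)", x$strategy_b),
    "trade-off (no strategy dominates)"
  )
  cat("  verdict                :", verdict, "\n")
  invisible(x)
}
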