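# Top-level interface: run the probabilistic sensitivity analysis for both
# stimulation strategies and compare them.

#' Probabilistic sensitivity analysis of both stimulation strategies
#'
#' The package's main entry point. Simulates `n` patients per strategy arm
#' (myo-inositol-supplemented rFSH stimulation versus rFSH alone) through
#' the up-to-three-cycle IVF program, summarizes mean cost, ongoing-pregnancy
#' rate and cost per pregnancy with their dispersions, and tests the
#' between-arm differences. The two arms use seeds `seed` and `seed + 1` of
#' the random stream, so a single integer reproduces the whole analysis.
#'
#' @inheritParams run_cohort
#' @param params Model parameterization; defaults to the built-in reference
#'   tables [ivf_parameters()].
#' @return An `ivf_psa` object: `cohorts` (one [`ivf_cohort`][run_cohort] per
#'   arm), `summaries` (one [`summary.ivf_cohort`] per arm), `comparison`
#'   (an [`ivf_comparison`][compare_strategies] of myo-inositol arm minus
#'   rFSH-only arm), and the run settings. Has `print`, `summary` and `plot`
#'   methods.
#' @examples
#' psa <- ivf_psa(n = 2000, seed = 1)
#' psa
#' @export
ivf_psa <- function(params = ivf_parameters(), n = 100000L, seed = 1L,
                    mode = c("table_faithful", "strict_embryo_gating"),
                    ohss_prob = 0, subcohort_size = 150L) {
  mode <- match.arg(mode)
  arms <- ivf_strategies()
  cohorts <- list(
    run_cohort(params, arms[1L], n = n, seed = seed, mode = mode,
               ohss_prob = ohss_prob, subcohort_size = subcohort_size),
    run_cohort(params, arms[2L], n = n, seed = seed + 1L, mode = mode,
               ohss_prob = ohss_prob, subcohort_size = subcohort_size)
  )
  names(cohorts) <- arms
  summaries <- lapply(cohorts, summary)
  structure(list(
    cohorts = cohorts,
    summaries = summaries,
    comparison = compare_strategies(cohorts[[1L]], cohorts[[2L]]),
    n = as.integer(n), seed = as.integer(seed), mode = mode,
    ohss_prob = ohss_prob, subcohort_size = as.integer(subcohort_size)
  ), class = "ivf_psa")
}

#' @export
print.ivf_psa <- function(x, ...) {
  cat(sprintf(
    "IVF program cost-effectiveness simulation (n = %d patients/arm, seed = %d, mode = %s)\n\n",
    x$n, x$seed, x$mode))
  for (s in x$summaries) print(s)
  cat("\n")
  print(x$comparison)
  invisible(x)
}

#' @export
summary.ivf_psa <- function(object, ...) {
  df <- do.call(rbind, lapply(object$summaries, function(s) {
    data.frame(
      strategy = s$strategy, n = s$n,
      mean_cost = s$mean_cost, sd_cost = s$sd_cost,
      pregnancy_rate = s$pregnancy_rate, sd_rate = s$sd_rate,
      cost_per_pregnancy = s$cost_per_pregnancy,
      sd_cost_per_pregnancy = s$sd_cost_per_pregnancy,
      stringsAsFactors = FALSE
    )
  }))
  rownames(df) <- NULL
  df
}

#' Cost-effectiveness scatter of sub-cohort outcomes
#'
#' Plots mean cost against ongoing-pregnancy rate for each disjoint
#' sub-cohort (of `subcohort_size` patients) of both arms — the simulation
#' analogue of a cost-effectiveness plane.
#'
#' @param x An `ivf_psa` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ivf_psa <- function(x, ...) {
  pts <- lapply(x$cohorts, function(co) {
    p <- co$patients
    k <- nrow(p) %/% co$subcohort_size
    idx <- seq_len(k * co$subcohort_size)
    grp <- rep(seq_len(k), each = co$subcohort_size)
    data.frame(rate = tapply(p$pregnant[idx], grp, mean),
               cost = tapply(p$cost[idx], grp, mean))
  })
  xlim <- range(unlist(lapply(pts, `[[`, "rate")))
  ylim <- range(unlist(lapply(pts, `[[`, "cost")))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "ongoing-pregnancy rate (sub-cohort)",
                 ylab = "mean cost per patient (EUR, sub-cohort)",
                 main = "Cost-effectiveness plane by sub-cohort", ...)
  cols <- c(rfsh_myoins = "#1b7837", rfsh = "#762a83")
  for (arm in names(pts)) {
    graphics::points(pts[[arm]]$rate, pts[[arm]]$cost, col = cols[[arm]],
                     pch = 16, cex = 0.5)
  }
  graphics::legend("topright", legend = names(pts), col = cols[names(pts)],
                   pch = 16, bty = "n")
  invisible(x)
}
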