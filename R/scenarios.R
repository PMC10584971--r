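# Scenario generator: random, degenerate and perturbed parameter tables so
# every stage of the engine is testable without external data, plus one-way
# deterministic sensitivity scans over the analytic oracle.

#' Generate a random, valid parameter scenario
#'
#' Emulates the statistical structure of the reference tables — independent
#' uniform min-max ranges — with randomized locations. Probability ranges
#' have widths drawn within `width_bounds` and are placed uniformly inside
#' `[0, 1]`; cost midpoints are drawn log-uniformly between 10 and 5000
#' euros (spanning the order of magnitude of real ART unit costs) with a
#' relative half-width drawn within `width_bounds`.
#'
#' @param seed Integer seed; the same seed always yields the same scenario.
#' @param width_bounds Length-2 numeric in `[0, 1]`: bounds on the range
#'   widths. `c(0, 0)` makes every range degenerate.
#' @return A validated `ivf_parameters` object.
#' @examples
#' s <- random_scenario(7)
#' nrow(validate_parameters(s)) # 0
#' @export
random_scenario <- function(seed, width_bounds = c(0.05, 0.4)) {
  stopifnot(length(width_bounds) == 2L,
            all(width_bounds >= 0), all(width_bounds <= 1),
            width_bounds[1L] <= width_bounds[2L])
  set.seed(seed)
  prob_range <- function() {
    w <- stats::runif(1L, width_bounds[1L], width_bounds[2L])
    lo <- stats::runif(1L, 0, 1 - w)
    c(lo, lo + w)
  }
  cost_range <- function() {
    mid <- exp(stats::runif(1L, log(10), log(5000)))
    rw <- stats::runif(1L, width_bounds[1L], width_bounds[2L])
    c(mid * (1 - rw), mid * (1 + rw))
  }
  params <- list(
    fresh = lapply(stats::setNames(nm = ivf_strategies()), function(arm) {
      lapply(stats::setNames(nm = .fresh_fields), function(f) prob_range())
    }),
    frozen = lapply(stats::setNames(nm = .frozen_fields), function(f) prob_range()),
    sequence = lapply(stats::setNames(nm = .sequence_fields), function(f) prob_range()),
    costs = lapply(stats::setNames(nm = .cost_fields), function(f) cost_range())
  )
  class(params) <- "ivf_parameters"
  assert_valid_parameters(params)
}

#' Degenerate parameter scenarios with known exact outcomes
#'
#' Edge-case parameterizations built from the reference tables:
#' `certain_success` pins every transition probability at 1 (ICSI share at
#' 0), so every patient conceives in cycle 1; `certain_failure` pins all
#' pregnancy probabilities at 0; `single_cycle_only` pins both continuation
#' probabilities at 0, reducing the program to one fresh cycle.
#'
#' @param kind One of `"certain_success"`, `"certain_failure"`,
#'   `"single_cycle_only"`.
#' @return A validated `ivf_parameters` object.
#' @export
degenerate_scenario <- function(kind = c("certain_success", "certain_failure",
                                         "single_cycle_only")) {
  kind <- match.arg(kind)
  params <- ivf_parameters()
  if (kind == "certain_success") {
    for (arm in ivf_strategies()) {
      for (f in .fresh_fields) {
        params$fresh[[arm]][[f]] <- if (f == "icsi_share") c(0, 0) else c(1, 1)
      }
    }
    for (f in .frozen_fields) params$frozen[[f]] <- c(1, 1)
    for (f in .sequence_fields) params$sequence[[f]] <- c(1, 1)
  } else if (kind == "certain_failure") {
    for (arm in ivf_strategies()) {
      params$fresh[[arm]]$ivf_pregnancy <- c(0, 0)
      params$fresh[[arm]]$icsi_pregnancy <- c(0, 0)
    }
    params$frozen$pregnancy_after_survival <- c(0, 0)
  } else {
    params$sequence$start_cycle2_after_failure <- c(0, 0)
    params$sequence$start_cycle3_after_failure <- c(0, 0)
  }
  assert_valid_parameters(params)
}

# the dotted parameter paths accepted by sensitivity_scan and overrides
parameter_paths <- function() {
  c(paste("fresh", .fresh_fields, sep = "."),
    paste("frozen", .frozen_fields, sep = "."),
    paste("sequence", .sequence_fields, sep = "."),
    paste("costs", .cost_fields, sep = "."))
}

#' One-way deterministic sensitivity scan
#'
#' Evaluates the analytic program outcomes over a grid of values for a
#' single parameter, holding every other parameter at the midpoint of its
#' range in `base`. Fresh-cycle parameters are varied in the arm given by
#' `strategy`.
#'
#' @param base An `ivf_parameters` object supplying all other parameters.
#' @param parameter_path Dotted path of the parameter to vary, e.g.
#'   `"fresh.icsi_share"`, `"sequence.start_cycle2_after_failure"`,
#'   `"costs.ivf_lab"`.
#' @param grid Numeric vector of point values for that parameter
#'   (fractions for probabilities, euros for costs).
#' @param strategy Strategy arm to evaluate.
#' @param ohss_prob Per-fresh-cycle OHSS cost probability (default 0).
#' @return A data frame with one row per grid value: `value`, `pregnancy`,
#'   `expected_cost`, `cost_per_pregnancy`.
#' @examples
#' sensitivity_scan(ivf_parameters(), "fresh.icsi_share", c(0.1, 0.3, 0.5))
#' @export
sensitivity_scan <- function(base, parameter_path, grid,
                             strategy = ivf_strategies(), ohss_prob = 0) {
  strategy <- match.arg(strategy)
  valid <- parameter_paths()
  if (!parameter_path %in% valid) {
    stop("unknown parameter path '", parameter_path, "'; valid paths are:\n  ",
         paste(valid, collapse = "\n  "), call. = FALSE)
  }
  parts <- strsplit(parameter_path, ".", fixed = TRUE)[[1L]]
  block <- parts[1L]; field <- parts[2L]
  is_cost <- block == "costs"
  if (is_cost) {
    if (any(grid < 0)) stop("cost grid values must be non-negative", call. = FALSE)
  } else if (any(grid < 0 | grid > 1)) {
    stop("probability grid values must lie in [0,1]", call. = FALSE)
  }
  pt <- midpoint_parameters(base)
  rows <- lapply(grid, function(v) {
    p <- pt
    if (block == "fresh") p$fresh[[strategy]][[field]] <- v else p[[block]][[field]] <- v
    o <- expected_program_outcomes(p, strategy, ohss_prob)
    data.frame(value = v, pregnancy = o$pregnancy,
               expected_cost = o$expected_cost,
               cost_per_pregnancy = o$cost_per_pregnancy)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter_path") <- parameter_path
  attr(out, "strategy") <- strategy
  out
}
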