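# Parameter tables: stage transition-probability ranges and unit-cost ranges.
# Every parameter is a closed interval c(lo, hi) sampled uniformly at each use;
# a degenerate range lo == hi pins the value.

#' Stimulation strategies compared by the model
#'
#' The two ovarian-stimulation arms: recombinant FSH with oral myo-inositol
#' supplementation (`"rfsh_myoins"`) and recombinant FSH alone (`"rfsh"`).
#'
#' @return Character vector of the two strategy identifiers.
#' @export
ivf_strategies <- function() c("rfsh_myoins", "rfsh")

# canonical field names, one per table row
.fresh_fields <- c(
  "oocyte_pickup", "usable_oocytes", "icsi_share",
  "ivf_fertilization", "ivf_transfer", "ivf_pregnancy",
  "icsi_fertilization", "icsi_transfer", "icsi_pregnancy"
)
.frozen_fields <- c("embryo_survival", "pregnancy_after_survival")
.sequence_fields <- c(
  "start_cycle2_after_failure", "fresh_share_cycle2",
  "start_cycle3_after_failure", "fresh_share_cycle3"
)
.cost_fields <- c(
  "stim_rfsh", "stim_rfsh_myoins", "other_hormones",
  "monitoring_ultrasounds", "consultations", "oocyte_pickup",
  "pickup_ultrasound", "ivf_lab", "fresh_et_ivf_catheter",
  "ohss_treatment", "icsi_procedure", "icsi_lab", "icsi_et_catheter",
  "freeze_and_thaw", "frozen_et_catheter"
)

#' Reference model parameterization
#'
#' The built-in parameter set for IVF programs in PCOS patients under the
#' Italian Health System: per-arm fresh-cycle transition-probability ranges,
#' shared frozen-cycle and cycle-sequencing probabilities, and unit-cost
#' ranges in euros. Probabilities are stored as fractions in `[0, 1]`;
#' the CSV representation (see [write_parameter_csv()]) uses percent.
#'
#' @return An object of class `ivf_parameters`: a nested list with components
#'   `fresh` (one list of nine probability ranges per strategy), `frozen`
#'   (two shared probability ranges), `sequence` (four shared continuation /
#'   fresh-share ranges), and `costs` (fifteen euro ranges). Each range is a
#'   numeric vector `c(lo, hi)`.
#' @seealso [validate_parameters()], [read_parameter_csv()],
#'   [parameter_dictionary()]
#' @examples
#' p <- ivf_parameters()
#' p$fresh$rfsh_myoins$oocyte_pickup
#' nrow(validate_parameters(p)) # 0
#' @export
ivf_parameters <- function() {
  fresh_myoins <- list(
    oocyte_pickup      = c(0.70, 0.80),
    usable_oocytes     = c(0.85, 0.95),
    icsi_share         = c(0.10, 0.50),
    ivf_fertilization  = c(0.35, 0.75),
    ivf_transfer       = c(0.75, 0.95),
    ivf_pregnancy      = c(0.20, 0.45),
    icsi_fertilization = c(0.85, 1.00),
    icsi_transfer      = c(0.85, 1.00),
    icsi_pregnancy     = c(0.20, 0.45)
  )
  fresh_rfsh <- list(
    oocyte_pickup      = c(0.70, 0.80),
    usable_oocytes     = c(0.80, 0.90),
    icsi_share         = c(0.10, 0.50),
    ivf_fertilization  = c(0.30, 0.70),
    ivf_transfer       = c(0.70, 0.90),
    ivf_pregnancy      = c(0.20, 0.45),
    icsi_fertilization = c(0.80, 1.00),
    icsi_transfer      = c(0.80, 1.00),
    icsi_pregnancy     = c(0.20, 0.45)
  )
  structure(list(
    fresh = list(rfsh_myoins = fresh_myoins, rfsh = fresh_rfsh),
    frozen = list(
      embryo_survival          = c(0.90, 1.00),
      pregnancy_after_survival = c(0.20, 0.45)
    ),
    sequence = list(
      start_cycle2_after_failure = c(0.70, 1.00),
      fresh_share_cycle2         = c(0.40, 0.60),
      start_cycle3_after_failure = c(0.30, 0.60),
      fresh_share_cycle3         = c(0.20, 0.30)
    ),
    costs = list(
      stim_rfsh              = c(1000, 2000),
      stim_rfsh_myoins       = c(900, 1900),
      other_hormones         = c(40, 360),
      monitoring_ultrasounds = c(90, 200),
      consultations          = c(60, 200),
      oocyte_pickup          = c(1000, 1000),
      pickup_ultrasound      = c(30, 30),
      ivf_lab                = c(300, 600),
      fresh_et_ivf_catheter  = c(100, 200),
      ohss_treatment         = c(90, 150),
      icsi_procedure         = c(500, 700),
      icsi_lab               = c(300, 700),
      icsi_et_catheter       = c(100, 200),
      freeze_and_thaw        = c(150, 500),
      frozen_et_catheter     = c(100, 200)
    )
  ), class = "ivf_parameters")
}

# one violation record per broken rule
.violation <- function(parameter, rule) {
  data.frame(parameter = parameter, rule = rule, stringsAsFactors = FALSE)
}

.check_range <- function(r, name, prob) {
  v <- list()
  if (!is.numeric(r) || length(r) != 2L || anyNA(r)) {
    return(.violation(name, "range must be two finite numbers c(lo, hi)"))
  }
  if (r[1L] > r[2L]) v <- c(v, list(.violation(name, "lo > hi")))
  if (prob) {
    if (r[1L] < 0 || r[2L] > 1) {
      v <- c(v, list(.violation(name, "probability out of [0,1]")))
    }
  } else if (r[1L] < 0) {
    v <- c(v, list(.violation(name, "cost must be non-negative")))
  }
  do.call(rbind, c(v, list(.violation(character(0), character(0)))))
}

#' Validate a model parameterization
#'
#' Checks every invariant of an `ivf_parameters` object: structural
#' completeness (both arms, all fields present), `lo <= hi` for every range,
#' probabilities within `[0, 1]`, and non-negative costs. Violations are
#' returned, not raised, so a loader can report all of them at once.
#'
#' @param params An `ivf_parameters` object (or a compatible nested list).
#' @return A data frame with columns `parameter` and `rule`, one row per
#'   violation; zero rows when the parameterization is valid.
#' @examples
#' bad <- ivf_parameters()
#' bad$frozen$embryo_survival <- c(1.1, 1.2)
#' validate_parameters(bad)
#' @export
validate_parameters <- function(params) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  blocks <- list(
    fresh = .fresh_fields, frozen = .frozen_fields,
    sequence = .sequence_fields, costs = .cost_fields
  )
  miss <- setdiff(names(blocks), names(params))
  if (length(miss)) {
    return(.violation(miss, rep("missing block", length(miss))))
  }
  arms <- ivf_strategies()
  if (!setequal(names(params$fresh), arms)) {
    add(.violation("fresh", "exactly two arms required: rfsh, rfsh_myoins"))
  }
  for (arm in intersect(arms, names(params$fresh))) {
    for (f in .fresh_fields) {
      key <- paste("fresh", arm, f, sep = ".")
      r <- params$fresh[[arm]][[f]]
      if (is.null(r)) add(.violation(key, "missing parameter")) else {
        add(.check_range(r, key, prob = TRUE))
      }
    }
  }
  for (blk in c("frozen", "sequence")) {
    for (f in blocks[[blk]]) {
      key <- paste(blk, f, sep = ".")
      r <- params[[blk]][[f]]
      if (is.null(r)) add(.violation(key, "missing parameter")) else {
        add(.check_range(r, key, prob = TRUE))
      }
    }
  }
  for (f in .cost_fields) {
    key <- paste("costs", f, sep = ".")
    r <- params$costs[[f]]
    if (is.null(r)) add(.violation(key, "missing parameter")) else {
      add(.check_range(r, key, prob = FALSE))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) .violation(character(0), character(0)) else res
}

# stop with a readable report when params are invalid
assert_valid_parameters <- function(params) {
  v <- validate_parameters(params)
  if (nrow(v)) {
    stop("invalid parameters:\n",
         paste0("  ", v$parameter, ": ", v$rule, collapse = "\n"),
         call. = FALSE)
  }
  invisible(params)
}

#' @export
print.ivf_parameters <- function(x, ...) {
  cat("IVF program parameter set (uniform min-max ranges)\n")
  df <- as.data.frame(x)
  df$min <- formatC(df$min, format = "g")
  df$max <- formatC(df$max, format = "g")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten a parameter set to a long table
#'
#' One row per parameter with columns `block`, `name`, `arm`, `min`, `max`,
#' `units`. Probabilities are expressed in percent (`units = "pct"`), costs
#' in euros (`units = "eur"`) — the same layout as the parameter CSV dialect.
#'
#' @param x An `ivf_parameters` object.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame in the parameter CSV layout.
#' @export
as.data.frame.ivf_parameters <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  push <- function(block, name, arm, r, units) {
    v <- if (units == "pct") round(100 * r, 9) else round(r, 9)
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, name = name, arm = arm,
      min = v[1L], max = v[2L], units = units, stringsAsFactors = FALSE
    )
  }
  for (arm in ivf_strategies()) {
    for (f in .fresh_fields) push("fresh", f, arm, x$fresh[[arm]][[f]], "pct")
  }
  for (f in .frozen_fields) push("frozen", f, "shared", x$frozen[[f]], "pct")
  for (f in .sequence_fields) push("sequence", f, "shared", x$sequence[[f]], "pct")
  for (f in .cost_fields) push("cost", f, "shared", x$costs[[f]], "eur")
  do.call(rbind, rows)
}

#' Write a parameter set to CSV
#'
#' Serializes to the documented CSV dialect: columns `block` (fresh | frozen |
#' sequence | cost), `name`, `arm` (strategy id or `shared`), `min`, `max`,
#' `units` (`pct` | `eur`). Probabilities are written in percent so the file
#' can be eyeballed against published tables.
#'
#' @param params An `ivf_parameters` object; validated before writing.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_parameter_csv()]
#' @export
write_parameter_csv <- function(params, path) {
  assert_valid_parameters(params)
  utils::write.csv(as.data.frame(params), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parameter set from CSV
#'
#' Parses the CSV dialect written by [write_parameter_csv()], converts percent
#' values to fractions, and validates the result. All validation violations
#' are reported together; missing rows and malformed numbers are reported
#' with the offending row.
#'
#' @param path Path to a parameter CSV file.
#' @return A validated `ivf_parameters` object.
#' @examples
#' f <- system.file("extdata", "ivf_parameters.csv", package = "ivfcea")
#' p <- read_parameter_csv(f)
#' @export
read_parameter_csv <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("block", "name", "arm", "min", "max", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parameter CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed number in column '", col, "' at data row ", bad[1L],
           " (", df$block[bad[1L]], "/", df$name[bad[1L]], ")", call. = FALSE)
    }
    v
  }
  mn <- num("min"); mx <- num("max")
  key <- paste(df$block, df$name, df$arm, sep = "|")
  lookup <- function(block, name, arm, units) {
    i <- match(paste(block, name, arm, sep = "|"), key)
    if (is.na(i)) {
      stop("parameter CSV is missing required row: block=", block,
           " name=", name, " arm=", arm, call. = FALSE)
    }
    r <- c(mn[i], mx[i])
    if (df$units[i] != units) {
      stop("row ", name, ": expected units '", units, "', found '",
           df$units[i], "'", call. = FALSE)
    }
    if (units == "pct") r / 100 else r
  }
  params <- list(
    fresh = lapply(stats::setNames(nm = ivf_strategies()), function(arm) {
      lapply(stats::setNames(nm = .fresh_fields), function(f) {
        lookup("fresh", f, arm, "pct")
      })
    }),
    frozen = lapply(stats::setNames(nm = .frozen_fields), function(f) {
      lookup("frozen", f, "shared", "pct")
    }),
    sequence = lapply(stats::setNames(nm = .sequence_fields), function(f) {
      lookup("sequence", f, "shared", "pct")
    }),
    costs = lapply(stats::setNames(nm = .cost_fields), function(f) {
      lookup("cost", f, "shared", "eur")
    })
  )
  class(params) <- "ivf_parameters"
  v <- validate_parameters(params)
  if (nrow(v)) {
    stop("parameter file fails validation:\n",
         paste0("  ", v$parameter, ": ", v$rule, collapse = "\n"),
         call. = FALSE)
  }
  params
}

#' Parameter dictionary
#'
#' Machine-readable mapping from each canonical parameter name to its
#' clinical label and units, as shipped in `inst/extdata/parameter_dictionary.csv`.
#'
#' @return A data frame with columns `block`, `name`, `label`, `units`.
#' @export
parameter_dictionary <- function() {
  f <- system.file("extdata", "parameter_dictionary.csv", package = "ivfcea")
  utils::read.csv(f, stringsAsFactors = FALSE)
}
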