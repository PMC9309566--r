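# Parameter-set loading, validation, dotted-path access and the PSA
# uncertainty registry.

#' Load a model parameter set from a YAML configuration file
#'
#' Reads the nested key/value configuration into a typed `parameter_set`:
#' age-banded rates become [age_banded_rate()] objects, 5-year mortality
#' schedules become [cumulative_schedule()] objects, and uncertain scalars
#' (maps with `value` and `sd` or `lo`/`hi`) are stored as their point value
#' with the uncertainty recorded in an attached registry used by the
#' probabilistic sensitivity analysis.
#'
#' @param path Path to a YAML file; defaults to the shipped base case.
#' @return A `parameter_set`: nested list with sections `economics`,
#'   `probabilities`, `utilities`, `costs`, `options`, and an `uncertainty`
#'   attribute (data frame of dotted paths with sd / interval bounds).
#' @examples
#' params <- default_parameters()
#' get_parameter(params, "probabilities.p_positive_test")
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- new.env(parent = emptyenv())
  reg$rows <- list()
  note <- function(path, sd = NA_real_, lo = NA_real_, hi = NA_real_) {
    reg$rows[[length(reg$rows) + 1L]] <- data.frame(
      path = path, sd = sd, lo = lo, hi = hi, stringsAsFactors = FALSE)
  }
  parse_node <- function(node, path) {
    if (!is.list(node)) return(node)
    if (!is.null(node$bands)) {
      b <- do.call(rbind, lapply(node$bands, function(bb) {
        data.frame(age_lo = bb$age_lo,
                   age_hi = if (is.null(bb$age_hi)) Inf else bb$age_hi,
                   p = bb$p,
                   lo = if (is.null(bb$lo)) NA_real_ else bb$lo,
                   hi = if (is.null(bb$hi)) NA_real_ else bb$hi,
                   sd = if (is.null(bb$sd)) NA_real_ else bb$sd)
      }))
      for (k in seq_len(nrow(b))) {
        if (!is.na(b$sd[k]) || !is.na(b$lo[k])) {
          note(sprintf("%s.bands[%d].p", path, k), b$sd[k], b$lo[k], b$hi[k])
        }
      }
      return(age_banded_rate(b$age_lo, b$age_hi, b$p,
                             lo = if (all(is.na(b$lo))) NULL else b$lo,
                             hi = if (all(is.na(b$hi))) NULL else b$hi,
                             sd = if (all(is.na(b$sd))) NULL else b$sd))
    }
    if (!is.null(node$cum)) {
      sch <- cumulative_schedule(as.numeric(node$cum),
                                 lo = node$lo, hi = node$hi, sd = node$sd)
      for (k in 1:5) {
        note(sprintf("%s.cum[%d]", path, k),
             if (is.null(node$sd)) NA_real_ else node$sd[k],
             if (is.null(node$lo)) NA_real_ else node$lo[k],
             if (is.null(node$hi)) NA_real_ else node$hi[k])
      }
      return(sch)
    }
    if (!is.null(node$value)) {
      note(path,
           if (is.null(node$sd)) NA_real_ else node$sd,
           if (is.null(node$lo)) NA_real_ else node$lo,
           if (is.null(node$hi)) NA_real_ else node$hi)
      return(node$value)
    }
    out <- lapply(names(node), function(nm) {
      parse_node(node[[nm]], if (nzchar(path)) paste0(path, ".", nm) else nm)
    })
    names(out) <- names(node)
    out
  }
  params <- parse_node(raw, "")
  attr(params, "uncertainty") <- do.call(rbind, reg$rows)
  attr(params, "source") <- normalizePath(path)
  class(params) <- "parameter_set"
  params
}

#' @rdname read_parameters
#' @export
default_parameters <- function() {
  read_parameters(system.file("extdata", "basecase.yaml", package = "hboccea",
                              mustWork = TRUE))
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("HBOC cost-effectiveness parameter set\n")
  cat(sprintf("  start age %d, horizon %d years, discount rate %.3g\n",
              x$economics$start_age, x$economics$horizon_years,
              x$economics$discount_rate))
  cat(sprintf("  %d uncertain quantities registered for PSA\n",
              nrow(psa_parameter_table(x))))
  invisible(x)
}

# --- dotted-path access ------------------------------------------------------

split_path <- function(path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  lapply(segs, function(s) {
    m <- regmatches(s, regexec("^([^\\[]+)(\\[([0-9]+)\\])?$", s))[[1]]
    if (!length(m)) stop("bad parameter path segment: ", s)
    list(name = m[2], idx = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_)
  })
}

#' Read or replace a value by dotted parameter path
#'
#' Paths use `.` between levels and `[k]` for vector elements or age-band
#' rows, e.g. `"economics.discount_rate"`, `"costs.bc_index_yearly[1]"`,
#' `"probabilities.well_to_bc_carrier.bands[2].p"`. `set_parameter()` returns
#' a modified copy; the input (and thus the base case) is never mutated.
#'
#' @param params A `parameter_set`.
#' @param path Dotted parameter path.
#' @param value Replacement value (numeric scalar, or numeric vector when the
#'   path names a whole schedule).
#' @return `get_parameter()`: the value; `set_parameter()`: the new
#'   `parameter_set`.
#' @export
get_parameter <- function(params, path) {
  segs <- split_path(path)
  x <- params
  for (sg in segs) {
    if (is.environment(x) || is.null(x)) stop("unknown parameter path: ", path)
    if (inherits(x, "age_banded_rate") && sg$name != "bands") {
      stop("unknown parameter path: ", path)
    }
    if (is.data.frame(x)) {
      x <- x[[sg$name]]
      if (!is.na(sg$idx)) x <- x[sg$idx]
      next
    }
    if (!sg$name %in% names(x)) stop("unknown parameter path: ", path)
    x <- x[[sg$name]]
    if (!is.na(sg$idx)) {
      if (is.data.frame(x)) x <- x[sg$idx, , drop = FALSE] else x <- x[sg$idx]
    }
  }
  x
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, path, value) {
  segs <- split_path(path)
  assign_rec <- function(x, segs) {
    sg <- segs[[1]]
    if (is.data.frame(x)) {
      if (length(segs) == 1) {
        if (!is.na(sg$idx)) x[sg$idx, sg$name] <- value else x[[sg$name]] <- value
        return(x)
      }
      stop("unknown parameter path: ", path)
    }
    if (!sg$name %in% names(x)) stop("unknown parameter path: ", path)
    if (length(segs) == 1) {
      if (!is.na(sg$idx)) x[[sg$name]][sg$idx] <- value else x[[sg$name]] <- value
      return(x)
    }
    child <- x[[sg$name]]
    if (!is.na(sg$idx) && is.data.frame(child[[segs[[2]]$name]])) {
      # e.g. bands[2].p: idx applies to the data frame row at the next level
    }
    if (!is.na(sg$idx) && !is.data.frame(child)) {
      stop("index not supported at interior path segment: ", sg$name)
    }
    x[[sg$name]] <- assign_rec(child, segs[-1])
    x
  }
  # special case: ...bands[k].col
  out <- tryCatch(assign_rec(params, normalize_band_segs(segs)),
                  error = function(e) stop(conditionMessage(e), call. = FALSE))
  attributes(out) <- attributes(params)
  out
}

# Rewrites [bands[k], p] so the index lands on the data frame row access.
normalize_band_segs <- function(segs) {
  if (length(segs) >= 2) {
    for (i in seq_len(length(segs) - 1)) {
      if (!is.na(segs[[i]]$idx) && segs[[i]]$name == "bands") {
        segs[[i + 1]]$idx <- segs[[i]]$idx
        segs[[i]]$idx <- NA_integer_
      }
    }
  }
  segs
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter model and returns findings rather
#' than raising: each violated invariant yields one row with the dotted path
#' of the offending parameter, a message and a severity.
#'
#' @param params A `parameter_set`.
#' @return A data frame with columns `path`, `message`, `severity`
#'   (zero rows when the set is valid).
#' @export
validate_parameters <- function(params) {
  findings <- list()
  flag <- function(path, message, severity = "error") {
    findings[[length(findings) + 1L]] <<- data.frame(
      path = path, message = message, severity = severity,
      stringsAsFactors = FALSE)
  }
  pr <- params$probabilities
  scalar_probs <- c("p_positive_test", "uptake_mastectomy", "uptake_oophorectomy",
                    "uptake_both", "well_to_bc_after_mastectomy",
                    "well_to_bc_after_both", "well_to_oc_carrier",
                    "well_to_oc_noncarrier", "well_to_oc_after_mastectomy",
                    "well_to_oc_after_oophorectomy", "well_to_oc_after_both",
                    "recurrence_bc_carrier", "recurrence_bc_noncarrier",
                    "bc_mortality", "bc_to_metastatic", "bc_to_oc")
  for (nm in scalar_probs) {
    v <- pr[[nm]]
    if (is.null(v)) { flag(paste0("probabilities.", nm), "missing"); next }
    if (v < 0 || v > 1) flag(paste0("probabilities.", nm), "probability outside [0, 1]")
  }
  upt <- pr$uptake_mastectomy + pr$uptake_oophorectomy + pr$uptake_both
  if (isTRUE(upt > 1)) {
    flag("probabilities.uptake_mastectomy", sprintf("uptake sum > 1 (%.3g)", upt))
  }
  for (nm in c("well_to_bc_carrier", "well_to_bc_noncarrier",
               "well_to_bc_after_oophorectomy", "all_cause_mortality")) {
    abr <- pr[[nm]]
    if (!inherits(abr, "age_banded_rate")) { flag(paste0("probabilities.", nm), "not an age-banded rate"); next }
    bad <- which(abr$bands$p < 0 | abr$bands$p > 1)
    for (k in bad) flag(sprintf("probabilities.%s.bands[%d].p", nm, k),
                        "probability outside [0, 1]")
    if (abr$bands$age_lo[1] > params$economics$start_age) {
      flag(paste0("probabilities.", nm), "bands do not cover the start age")
    }
  }
  for (nm in c("metastatic_death", "oc_death")) {
    sch <- pr[[nm]]
    cum <- if (inherits(sch, "cumulative_schedule")) sch$cum else sch
    if (length(cum) != 5) flag(paste0("probabilities.", nm), "schedule must have 5 years")
    if (any(cum < 0 | cum > 1)) flag(paste0("probabilities.", nm), "cumulative value outside [0, 1]")
    bad <- which(diff(cum) < 0)
    if (length(bad)) flag(sprintf("probabilities.%s.cum[%d]", nm, bad[1] + 1),
                          "cumulative schedule not non-decreasing")
  }
  ut <- params$utilities
  for (nm in grep("^multiplier|^baseline", names(ut), value = TRUE)) {
    if (ut[[nm]] <= 0 || ut[[nm]] > 1) {
      flag(paste0("utilities.", nm), "utility value outside (0, 1]")
    }
  }
  for (nm in grep("^recovery_increment", names(ut), value = TRUE)) {
    if (ut[[nm]] < 0) flag(paste0("utilities.", nm), "recovery increment < 0")
  }
  co <- params$costs
  for (nm in setdiff(names(co), "psa_cost_sd_fraction")) {
    if (any(co[[nm]] < 0)) flag(paste0("costs.", nm), "negative cost")
  }
  for (nm in c("bc_index_yearly", "bc_relative_yearly", "metastatic_yearly", "oc_yearly")) {
    if (length(co[[nm]]) != 5) flag(paste0("costs.", nm), "yearly schedule must have 5 entries")
  }
  if (co$n_relatives_per_index < 1) flag("costs.n_relatives_per_index", "must be >= 1")
  ec <- params$economics
  if (ec$discount_rate < 0) flag("economics.discount_rate", "discount_rate < 0")
  if (ec$horizon_years < 1) flag("economics.horizon_years", "horizon < 1")
  if (ec$cycle_length != 1) flag("economics.cycle_length", "only 1-year cycles supported")
  if (length(findings)) do.call(rbind, findings) else
    data.frame(path = character(), message = character(), severity = character(),
               stringsAsFactors = FALSE)
}

# --- PSA uncertainty registry ------------------------------------------------

#' Table of uncertain parameters entering the probabilistic analysis
#'
#' Probabilities and utilities with printed uncertainty (sd or 95% interval)
#' are beta-distributed; every cost, including the derived per-woman test
#' cost, is gamma-distributed with a 40% standard deviation. Means are taken
#' from the current values in `params`, so deterministic scenario edits
#' propagate.
#'
#' @param params A `parameter_set`.
#' @return Data frame with columns `path`, `mean`, `sd`, `family`.
#' @export
psa_parameter_table <- function(params) {
  reg <- attr(params, "uncertainty")
  rows <- list()
  if (!is.null(reg)) {
    for (i in seq_len(nrow(reg))) {
      sd <- reg$sd[i]
      if (is.na(sd)) {
        if (is.na(reg$lo[i])) next
        sd <- ci_to_sd(reg$lo[i], reg$hi[i])
      }
      if (sd <= 0) next
      m <- get_parameter(params, reg$path[i])
      if (m <= 0 || m >= 1) next   # beta support; degenerate means stay fixed
      rows[[length(rows) + 1L]] <- data.frame(path = reg$path[i], mean = m,
                                              sd = sd, family = "beta")
    }
  }
  frac <- params$costs$psa_cost_sd_fraction
  cost_paths <- c("costs.intensive_screening_annual", "costs.standard_care_annual",
                  "costs.surgery_mastectomy", "costs.surgery_oophorectomy",
                  "costs.surgery_both",
                  sprintf("costs.bc_index_yearly[%d]", 1:5),
                  sprintf("costs.bc_relative_yearly[%d]", 1:5),
                  sprintf("costs.metastatic_yearly[%d]", 1:5),
                  sprintf("costs.oc_yearly[%d]", 1:5))
  for (p in cost_paths) {
    m <- get_parameter(params, p)
    if (m <= 0) next
    rows[[length(rows) + 1L]] <- data.frame(path = p, mean = m, sd = frac * m,
                                            family = "gamma")
  }
  tc <- test_cost_per_woman(params$costs$cost_index_test,
                            params$costs$cost_relative_test,
                            params$costs$n_relatives_per_index)
  rows[[length(rows) + 1L]] <- data.frame(path = "costs.test_cost_per_woman",
                                          mean = tc, sd = frac * tc,
                                          family = "gamma")
  do.call(rbind, rows)
}

#' Draw a set of Monte Carlo parameter samples
#'
#' One independent draw stream per uncertain parameter, in the fixed order of
#' [psa_parameter_table()], so results are reproducible for a given seed set
#' by the caller.
#'
#' @param params A `parameter_set`.
#' @param n Number of draws.
#' @return Named list mapping dotted parameter paths to numeric vectors of
#'   length `n`.
#' @export
draw_psa_samples <- function(params, n) {
  tab <- psa_parameter_table(params)
  draws <- vector("list", nrow(tab))
  names(draws) <- tab$path
  for (i in seq_len(nrow(tab))) {
    spec <- fit_distribution(tab$mean[i], sd = tab$sd[i], family = tab$family[i])
    draws[[i]] <- draw_distribution(spec, n)
  }
  draws
}
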