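# Typed containers and transformations for model inputs: age-banded rates,
# cumulative mortality schedules, test-cost averaging and PSA distribution fits.

#' Age-banded annual rate
#'
#' An annual event probability that varies by age band. Bands must be
#' contiguous and non-overlapping from the model start age upward; the last
#' band may be open-ended (`age_hi = Inf`) and then applies to all older ages.
#'
#' @param age_lo,age_hi Integer vectors of band bounds in years (inclusive;
#'   use `Inf` or `NA` for an open last band).
#' @param p Annual probabilities in `[0, 1]`, one per band.
#' @param lo,hi Optional per-band 95% interval bounds.
#' @param sd Optional per-band standard deviations.
#' @return An object of class `age_banded_rate`.
#' @examples
#' abr <- age_banded_rate(c(30, 35), c(34, Inf), c(0.012, 0.016))
#' rate_lookup(abr, 52)
#' @export
age_banded_rate <- function(age_lo, age_hi, p, lo = NULL, hi = NULL, sd = NULL) {
  age_hi[is.na(age_hi)] <- Inf
  stopifnot(length(age_lo) == length(age_hi), length(p) == length(age_lo))
  if (any(p < 0 | p > 1)) stop("age_banded_rate: probabilities must be in [0, 1]")
  if (is.unsorted(age_lo, strictly = TRUE)) stop("age_banded_rate: bands must be ordered")
  if (length(age_lo) > 1 && any(age_lo[-1] != head(age_hi, -1) + 1)) {
    stop("age_banded_rate: bands must be contiguous (age_lo[k+1] == age_hi[k] + 1)")
  }
  bands <- data.frame(age_lo = age_lo, age_hi = age_hi, p = p)
  if (!is.null(lo)) bands$lo <- lo
  if (!is.null(hi)) bands$hi <- hi
  if (!is.null(sd)) bands$sd <- sd
  structure(list(bands = bands), class = "age_banded_rate")
}

#' Look up the annual rate applying at a given age
#'
#' @param x An [age_banded_rate()].
#' @param age Age (or vector of ages) in years.
#' @return Numeric vector of annual probabilities.
#' @export
rate_lookup <- function(x, age) {
  stopifnot(inherits(x, "age_banded_rate"))
  idx <- band_index(x, age)
  x$bands$p[idx]
}

# Band index for an age; errors below the first band, clamps into the open tail.
band_index <- function(x, age) {
  b <- x$bands
  if (any(age < b$age_lo[1])) stop("rate_lookup: age below first band")
  idx <- findInterval(age, b$age_lo)
  if (any(age > b$age_hi[idx])) stop("rate_lookup: age falls in a gap between bands")
  idx
}

#' @export
print.age_banded_rate <- function(x, ...) {
  cat("Age-banded annual rate (", nrow(x$bands), " bands)\n", sep = "")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Cumulative event schedule for tunnel years 1-5
#'
#' Cumulative probabilities of an event (here: death) by the end of years 1..5
#' since state entry, as produced by a Kaplan-Meier analysis. Must be
#' non-decreasing.
#'
#' @param cum Numeric vector of 5 cumulative probabilities.
#' @param lo,hi,sd Optional per-year uncertainty (95% bounds or sd).
#' @return An object of class `cumulative_schedule`.
#' @export
cumulative_schedule <- function(cum, lo = NULL, hi = NULL, sd = NULL) {
  if (length(cum) != 5) stop("cumulative_schedule: exactly 5 yearly values required")
  if (any(cum < 0 | cum > 1)) stop("cumulative_schedule: values must be in [0, 1]")
  bad <- which(diff(cum) < 0)
  if (length(bad)) {
    stop(sprintf("cumulative_schedule: non-monotone at year %d (%.4g > %.4g)",
                 bad[1] + 1, cum[bad[1]], cum[bad[1] + 1]))
  }
  structure(list(cum = cum, lo = lo, hi = hi, sd = sd), class = "cumulative_schedule")
}

#' Convert a cumulative schedule to per-cycle conditional probabilities
#'
#' The printed 5-year mortality schedules are cumulative; the Markov engine
#' consumes the probability of the event in year `t` conditional on having
#' survived years `1..t-1`:
#' `cond[t] = (cum[t] - cum[t-1]) / (1 - cum[t-1])`.
#'
#' Applying `cond` sequentially to a unit cohort reproduces `cum` exactly
#' (round-trip identity). If the cumulative probability reaches 1 before year
#' 5, the remaining conditional values are set to 1 with a warning.
#'
#' @param sched A [cumulative_schedule()] or a bare numeric vector of 5
#'   non-decreasing cumulative probabilities.
#' @param tail One of `"hold"` (years beyond 5 keep `cond[5]`) or `"none"`
#'   (no event risk after year 5); stored alongside the values.
#' @return An object of class `conditional_schedule`: list with `cond`
#'   (numeric 5) and `tail`.
#' @examples
#' cumulative_to_conditional(c(0.37, 0.61, 0.76, 0.85, 0.90))
#' @export
cumulative_to_conditional <- function(sched, tail = c("hold", "none")) {
  tail <- match.arg(tail)
  if (is.numeric(sched)) sched <- cumulative_schedule(sched)
  stopifnot(inherits(sched, "cumulative_schedule"))
  cum <- sched$cum
  prev <- c(0, cum[-5])
  cond <- numeric(5)
  saturated <- prev >= 1
  if (any(saturated)) {
    warning("cumulative schedule reaches 1 before year 5; later conditional values set to 1")
    cond[saturated] <- 1
  }
  ok <- !saturated
  cond[ok] <- (cum[ok] - prev[ok]) / (1 - prev[ok])
  structure(list(cond = cond, tail = tail), class = "conditional_schedule")
}

#' @export
print.conditional_schedule <- function(x, ...) {
  cat("Per-cycle conditional probabilities, tunnel years 1-5:\n")
  print(round(x$cond, 6))
  cat("Tail policy beyond year 5:", x$tail, "\n")
  invisible(x)
}

#' Mean genetic-test cost per woman under family-based testing
#'
#' The index case carries the full sequencing + rearrangement analysis cost;
#' relatives are tested for the family's known variant at a much lower cost.
#' The per-woman unit cost averages one index over her tested relatives:
#' `(cost_index + n_relatives * cost_relative) / n_relatives`.
#'
#' @param cost_index Cost of testing the index case (R$).
#' @param cost_relative Cost of testing one relative (R$).
#' @param n_relatives Number of relatives tested per index case (>= 1).
#' @return Unit cost per tested woman in R$.
#' @examples
#' test_cost_per_woman(1800, 235, 2) # 1135
#' @export
test_cost_per_woman <- function(cost_index, cost_relative, n_relatives) {
  if (any(n_relatives < 1)) {
    stop("test_cost_per_woman: n_relatives must be >= 1 (index-only testing is not modelled)")
  }
  if (any(cost_index < 0) || any(cost_relative < 0)) {
    stop("test_cost_per_woman: costs must be non-negative")
  }
  (cost_index + n_relatives * cost_relative) / n_relatives
}

#' Convert a printed 95% interval to a standard deviation
#'
#' Intervals printed alongside point estimates are interpreted as 95%
#' confidence intervals, so `sd = (hi - lo) / 3.92`.
#'
#' @param lo,hi Interval bounds.
#' @return Standard deviation.
#' @export
ci_to_sd <- function(lo, hi) (hi - lo) / 3.92

#' Fit a beta or gamma distribution by the method of moments
#'
#' Beta: `alpha = m * (m(1-m)/s^2 - 1)`, `beta = (1-m) * (m(1-m)/s^2 - 1)`.
#' Gamma: `shape = (m/s)^2`, `scale = s^2/m`. If only a `(lo, hi)` range is
#' given the sd is derived with [ci_to_sd()]. An infeasible beta sd
#' (`s^2 >= m(1-m)`) is shrunk to 0.999 of the feasible bound with a warning.
#'
#' @param mean Target mean (in `(0,1)` for beta, `> 0` for gamma).
#' @param sd Target standard deviation (optional if `lo`/`hi` given).
#' @param lo,hi Optional 95% interval from which sd is derived.
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @return A `distribution_spec`: list with `family`, the fitted parameters,
#'   and the input `mean` and (possibly shrunk) `sd`.
#' @examples
#' fit_distribution(0.5, sd = 0.1, family = "beta")   # alpha = beta = 12
#' fit_distribution(1135, sd = 454, family = "gamma") # shape 6.25, scale 181.6
#' @export
fit_distribution <- function(mean, sd = NULL, lo = NULL, hi = NULL,
                             family = c("beta", "gamma", "fixed")) {
  family <- match.arg(family)
  if (family == "fixed") {
    return(structure(list(family = "fixed", mean = mean, sd = 0),
                     class = "distribution_spec"))
  }
  if (is.null(sd)) {
    if (is.null(lo) || is.null(hi)) stop("fit_distribution: provide sd or (lo, hi)")
    sd <- ci_to_sd(lo, hi)
  }
  if (sd <= 0) stop("fit_distribution: sd must be positive (use family = 'fixed')")
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) stop("fit_distribution: beta requires mean in (0, 1)")
    vmax <- mean * (1 - mean)
    if (sd^2 >= vmax) {
      sd <- 0.999 * sqrt(vmax)
      warning(sprintf("beta sd infeasible for mean %.4g; shrunk to %.4g", mean, sd))
    }
    nu <- mean * (1 - mean) / sd^2 - 1
    spec <- list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu,
                 mean = mean, sd = sd)
  } else {
    if (mean <= 0) stop("fit_distribution: gamma requires mean > 0")
    spec <- list(family = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean,
                 mean = mean, sd = sd)
  }
  structure(spec, class = "distribution_spec")
}

#' Draw random variates from a fitted distribution spec
#'
#' @param spec A `distribution_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"))
  switch(spec$family,
    fixed = rep(spec$mean, n),
    beta  = rbeta(n, spec$shape1, spec$shape2),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale)
  )
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("%s distribution: mean %.6g, sd %.6g\n", x$family, x$mean, x$sd))
  if (x$family == "beta") cat(sprintf("  shape1 %.6g, shape2 %.6g\n", x$shape1, x$shape2))
  if (x$family == "gamma") cat(sprintf("  shape %.6g, scale %.6g\n", x$shape, x$scale))
  invisible(x)
}
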