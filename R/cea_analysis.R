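# Incremental analysis, one-way deterministic (tornado) sensitivity analysis,
# and probabilistic sensitivity analysis with CEAC and INMB curves.

#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes incremental discounted cost, QALYs and life years on the unrounded
#' strategy totals, classifies dominance from the signs of the increments, and
#' reports ICERs per QALY and per life year gained for the trade-off case.
#'
#' @param reference `strategy_result` of the strategy being evaluated
#'   (here: testing).
#' @param comparator `strategy_result` of the comparator (no testing).
#' @return A `ce_result`: list with per-strategy totals, `d_cost`, `d_qaly`,
#'   `d_ly`, `icer_qaly`, `icer_ly` and a `dominance` flag (`"dominant"`,
#'   `"dominated"` or `"tradeoff"`).
#' @export
compute_icer <- function(reference, comparator) {
  stopifnot(inherits(reference, "strategy_result"),
            inherits(comparator, "strategy_result"))
  d_cost <- reference$cost[1] - comparator$cost[1]
  d_qaly <- reference$qaly[1] - comparator$qaly[1]
  d_ly <- reference$ly[1] - comparator$ly[1]
  if (abs(d_qaly) < 1e-12) {
    dominance <- if (d_cost > 0) "dominated" else if (d_cost < 0) "dominant" else "tradeoff"
    icer_qaly <- icer_ly <- NA_real_
    if (dominance == "tradeoff") icer_qaly <- icer_ly <- 0
  } else if (d_cost >= 0 && d_qaly > 0) {
    dominance <- "tradeoff"
    icer_qaly <- d_cost / d_qaly
    icer_ly <- if (abs(d_ly) < 1e-12) NA_real_ else d_cost / d_ly
  } else if (d_cost <= 0 && d_qaly < 0) {
    dominance <- "tradeoff"                 # reference cheaper and worse
    icer_qaly <- d_cost / d_qaly
    icer_ly <- if (abs(d_ly) < 1e-12) NA_real_ else d_cost / d_ly
  } else if (d_cost <= 0) {
    dominance <- "dominant"
    icer_qaly <- icer_ly <- NA_real_
  } else {
    dominance <- "dominated"
    icer_qaly <- icer_ly <- NA_real_
  }
  structure(list(reference = reference$arm, comparator = comparator$arm,
                 cost = c(reference = reference$cost[1], comparator = comparator$cost[1]),
                 qaly = c(reference = reference$qaly[1], comparator = comparator$qaly[1]),
                 ly = c(reference = reference$ly[1], comparator = comparator$ly[1]),
                 d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                 icer_qaly = icer_qaly, icer_ly = icer_ly,
                 dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$reference, x$comparator))
  cat(sprintf("  incremental cost R$ %.2f, QALYs %.5f, LYs %.5f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$dominance == "tradeoff") {
    cat(sprintf("  ICER: R$ %.2f per QALY, R$ %.2f per LY gained\n",
                x$icer_qaly, x$icer_ly))
  } else {
    cat("  dominance:", x$dominance, "\n")
  }
  invisible(x)
}

#' Evaluate both arms and their incremental result for a parameter set
#'
#' Convenience wrapper used throughout the deterministic analyses.
#'
#' @param params A `parameter_set`.
#' @return A `ce_result` of testing vs no testing.
#' @export
evaluate_cea <- function(params) {
  compute_icer(evaluate_strategy(params, "testing"),
               evaluate_strategy(params, "no_testing"))
}

# --- deterministic sensitivity analysis --------------------------------------

#' The shipped one-way sensitivity scenarios
#'
#' Reads the scenario configuration (parameter path, low and high value)
#' shipped with the package: discount rate 0 / 0.10; relatives tested per
#' index 4 / 1 (unit test cost R$ 685 / 2,035); breast-cancer risk after both
#' surgeries 0 / 0.08; ovarian-cancer risk after oophorectomy 0.004 / 0.03;
#' index breast-cancer treatment costs -40% / +40%; and the three surgery
#' uptake probabilities across their 95% intervals.
#'
#' @param file Optional path to an alternative scenario CSV with columns
#'   `scenario`, `path`, `low`, `high` (values `;`-joined for schedules).
#' @return Data frame with list-columns `low` and `high` holding numeric
#'   values.
#' @export
dsa_scenarios <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "dsa_scenarios.csv", package = "hboccea",
                        mustWork = TRUE)
  }
  raw <- read.csv(file, stringsAsFactors = FALSE)
  parse_vals <- function(s) lapply(strsplit(as.character(s), ";"), as.numeric)
  raw$low <- parse_vals(raw$low)
  raw$high <- parse_vals(raw$high)
  raw
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each scenario the base parameter set is cloned, the parameter at the
#' dotted path is set to its low and high value in turn, both arms are
#' re-evaluated and the ICER per QALY recorded. The base case is never
#' mutated. Output is sorted by tornado bar width (|ICER_high - ICER_low|)
#' descending.
#'
#' @param params A `parameter_set`.
#' @param scenarios Scenario table from [dsa_scenarios()].
#' @return A `dsa_result` data frame: `scenario`, `path`, `low`, `high`,
#'   `icer_low`, `icer_high`, `width`, plus the base ICER as attribute
#'   `icer_base`.
#' @export
run_dsa <- function(params, scenarios = dsa_scenarios()) {
  for (p in scenarios$path) get_parameter(params, p)   # fail fast on bad paths
  base <- evaluate_cea(params)
  one <- function(path, value) {
    evaluate_cea(set_parameter(params, path, value))$icer_qaly
  }
  icer_low <- icer_high <- numeric(nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    icer_low[i] <- one(scenarios$path[i], scenarios$low[[i]])
    icer_high[i] <- one(scenarios$path[i], scenarios$high[[i]])
  }
  out <- data.frame(scenario = scenarios$scenario, path = scenarios$path,
                    low = vapply(scenarios$low, paste, "", collapse = ";"),
                    high = vapply(scenarios$high, paste, "", collapse = ";"),
                    icer_low = icer_low, icer_high = icer_high,
                    width = abs(icer_high - icer_low),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base$icer_qaly
  class(out) <- c("dsa_result", "data.frame")
  out
}

# --- probabilistic sensitivity analysis --------------------------------------

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter independently from its fitted beta (
#' probabilities, utilities) or gamma (costs, 40% sd) distribution, re-runs
#' both arms per draw, and summarises the incremental cost and QALY samples
#' as a cost-effectiveness acceptability curve and an incremental net
#' monetary benefit curve over a willingness-to-pay grid.
#'
#' @param params A `parameter_set`.
#' @param n_samples Number of Monte Carlo draws (default 10,000).
#' @param seed RNG seed; the run is reproducible given the seed.
#' @param wtp_grid Willingness-to-pay grid in R$/QALY.
#' @return A `psa_result`: list with `d_cost`, `d_qaly` (length `n_samples`),
#'   `ceac` (data frame `wtp`, `probability`), `inmb` (data frame `wtp`,
#'   `inmb`), `n_samples`, `seed`.
#' @export
run_psa <- function(params, n_samples = 10000, seed = 1,
                    wtp_grid = seq(0, 150000, by = 500)) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  draws <- draw_psa_samples(params, n_samples)
  test <- evaluate_strategy(params, "testing", draws)
  notest <- evaluate_strategy(params, "no_testing", draws)
  d_cost <- test$cost - notest$cost
  d_qaly <- test$qaly - notest$qaly
  ceac <- vapply(wtp_grid, function(w) mean(w * d_qaly - d_cost > 0), 0)
  inmb <- wtp_grid * mean(d_qaly) - mean(d_cost)
  structure(list(d_cost = d_cost, d_qaly = d_qaly,
                 ceac = data.frame(wtp = wtp_grid, probability = ceac),
                 inmb = data.frame(wtp = wtp_grid, inmb = inmb),
                 n_samples = n_samples, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo samples (seed %s)\n", x$n_samples,
              format(x$seed)))
  cat(sprintf("  mean incremental cost R$ %.2f, mean incremental QALYs %.5f\n",
              mean(x$d_cost), mean(x$d_qaly)))
  i <- which.min(abs(x$ceac$wtp - 25000))
  cat(sprintf("  P(cost-effective at WTP 25,000) = %.4f\n",
              x$ceac$probability[i]))
  invisible(x)
}

#' Probability the strategy is cost-effective at a given willingness-to-pay
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay in R$/QALY (must lie on the grid).
#' @return Probability in `[0, 1]`.
#' @export
ceac_at <- function(psa, wtp) {
  i <- match(wtp, psa$ceac$wtp)
  if (is.na(i)) stop("wtp not on the CEAC grid")
  psa$ceac$probability[i]
}

#' Smallest willingness-to-pay at which the strategy is acceptably likely
#' to be cost-effective
#'
#' Scans the CEAC grid for the first WTP with probability at or above `p`.
#'
#' @param psa A `psa_result`.
#' @param p Target probability (default 0.5).
#' @return The WTP in R$/QALY, or `Inf` with a warning when the curve never
#'   reaches `p` on the grid.
#' @export
ceac_threshold <- function(psa, p = 0.5) {
  hit <- which(psa$ceac$probability >= p)
  if (!length(hit)) {
    warning("CEAC never reaches the target probability on the grid (above grid max)")
    return(Inf)
  }
  psa$ceac$wtp[hit[1]]
}
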