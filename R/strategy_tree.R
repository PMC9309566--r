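# Decision-tree arms expanded into weighted subcohorts and aggregated into
# per-strategy discounted totals.

#' Expand a decision-tree arm into weighted subcohorts
#'
#' The testing arm splits into women testing negative and, among the positive
#' fraction, the four prevention choices (surveillance as the residual of the
#' surgery uptakes). The no-testing arm is an untested mixture of carriers and
#' non-carriers at the mutation prevalence. Weights sum to 1 per arm.
#'
#' @param params A `parameter_set`.
#' @param arm `"testing"` or `"no_testing"`.
#' @return List of [subcohort()] objects.
#' @export
expand_arm <- function(params, arm = c("testing", "no_testing")) {
  arm <- match.arg(arm)
  pr <- params$probabilities
  ppos <- pr$p_positive_test
  um <- pr$uptake_mastectomy; uo <- pr$uptake_oophorectomy; ub <- pr$uptake_both
  if (um + uo + ub > 1) stop("prophylaxis uptake probabilities sum to more than 1")
  if (arm == "testing") {
    subs <- list(
      subcohort("testing", "negative", "negative", FALSE, "standard_care",
                1 - ppos),
      subcohort("testing", "positive_surveillance", "positive", TRUE,
                "surveillance", ppos * (1 - um - uo - ub)),
      subcohort("testing", "positive_mastectomy", "positive", TRUE,
                "mastectomy", ppos * um),
      subcohort("testing", "positive_oophorectomy", "positive", TRUE,
                "oophorectomy", ppos * uo),
      subcohort("testing", "positive_both", "positive", TRUE, "both", ppos * ub))
    subs <- Filter(function(s) s$weight > 0, subs)
  } else {
    subs <- list(
      subcohort("no_testing", "untested_carrier", "untested", TRUE,
                "standard_care", ppos),
      subcohort("no_testing", "untested_noncarrier", "untested", FALSE,
                "standard_care", 1 - ppos))
  }
  subs
}

# Per-draw weight vector for a subcohort (uptakes may be sampled in the PSA).
subcohort_weight <- function(params, sub, draws = NULL) {
  ppos <- params$probabilities$p_positive_test   # no printed uncertainty
  um <- pval(params, draws, "probabilities.uptake_mastectomy")
  uo <- pval(params, draws, "probabilities.uptake_oophorectomy")
  ub <- pval(params, draws, "probabilities.uptake_both")
  switch(sub$label,
    negative = 1 - ppos,
    positive_surveillance = ppos * (1 - um - uo - ub),
    positive_mastectomy = ppos * um,
    positive_oophorectomy = ppos * uo,
    positive_both = ppos * ub,
    untested_carrier = ppos,
    untested_noncarrier = 1 - ppos,
    stop("unknown subcohort label: ", sub$label))
}

#' Evaluate one strategy arm
#'
#' Runs the Markov engine for every subcohort of the arm and aggregates
#' weight-weighted discounted totals. In the testing arm the per-woman genetic
#' test cost is charged once at cycle 0 to every member (the test must be
#' performed to learn the result), and prophylactic surgery costs are charged
#' at cycle 0 to the respective subcohorts.
#'
#' @param params A `parameter_set`.
#' @param arm `"testing"` or `"no_testing"`.
#' @param draws Optional Monte Carlo samples from [draw_psa_samples()]; totals
#'   are then vectors over draws.
#' @return A `strategy_result`: list with `arm`, `cost`, `qaly`, `ly` and a
#'   per-subcohort `breakdown` data frame (base-case weights and totals).
#' @export
evaluate_strategy <- function(params, arm = c("testing", "no_testing"),
                              draws = NULL) {
  arm <- match.arg(arm)
  subs <- expand_arm(params, arm)
  ec <- params$economics
  n <- if (is.null(draws) || !length(draws)) 1L else max(lengths(draws))
  cost <- qaly <- ly <- numeric(n)
  wsum <- numeric(n)
  rows <- list()
  for (sub in subs) {
    inp <- subcohort_inputs(params, sub, draws)
    check_outflows(inp)
    res <- run_model_core(inp, ec)
    w <- rep_len(subcohort_weight(params, sub, draws), n)
    cost <- cost + w * res$cost
    qaly <- qaly + w * res$qaly
    ly <- ly + w * res$ly
    wsum <- wsum + w
    rows[[sub$label]] <- data.frame(
      label = sub$label, weight = sub$weight,
      cost = res$cost[1], qaly = res$qaly[1], ly = res$ly[1])
  }
  if (any(abs(wsum - 1) > 1e-9)) stop("subcohort weights do not sum to 1")
  structure(list(arm = arm, cost = cost, qaly = qaly, ly = ly,
                 breakdown = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s': cost R$ %.2f, %.4f QALYs, %.4f LYs\n",
              x$arm, x$cost[1], x$qaly[1], x$ly[1]))
  print(transform(x$breakdown, cost = round(cost, 2), qaly = round(qaly, 4),
                  ly = round(ly, 4)), row.names = FALSE)
  invisible(x)
}
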