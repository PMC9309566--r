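# Tunnel-expanded state space, transition matrices, cohort trace and
# discounted accumulation of costs, QALYs and life years.
#
# The engine has two equivalent execution paths: an explicit transition-matrix
# path (build_transition_matrix / run_trace) used for inspection, export and
# invariant testing, and a vectorised path (run_model_core) that evaluates
# many parameter draws simultaneously for the probabilistic analysis. Their
# agreement is asserted in the test suite.

# State indexing ---------------------------------------------------------------

#' The tunnel-expanded Markov state space
#'
#' Base states well / non-metastatic breast cancer / metastatic breast cancer /
#' ovarian cancer / post-breast-cancer / post-ovarian-cancer / death, with the
#' cancer follow-up years expanded into 5-year tunnel states so that costs,
#' utilities and mortality can depend on time since diagnosis. From year 6 the
#' cohort sits in the steady post-cancer (or metastatic) state.
#'
#' @return Character vector of the 20 expanded state labels, in matrix order.
#' @export
state_space <- function() {
  c("well",
    "bc_y1", paste0("post_bc_y", 2:5), "post_bc",
    paste0("met_y", 1:5), "met",
    "oc_y1", paste0("post_oc_y", 2:5), "post_oc",
    "death")
}

.S <- 20L
.I <- list(well = 1L, bc1 = 2L, pbc = 3:6, pbcs = 7L,
           met = 8:12, mets = 13L, oc1 = 14L, poc = 15:18, pocs = 19L,
           dead = 20L)

# Subcohort constructor --------------------------------------------------------

#' Define a model subcohort
#'
#' A homogeneous slice of the decision tree: one arm, one test result, one
#' carrier status and one prevention choice.
#'
#' @param arm `"testing"` or `"no_testing"`.
#' @param label Short identifier used in outputs.
#' @param test_result `"positive"`, `"negative"` or `"untested"`.
#' @param carrier Logical: true BRCA1/2 carrier status.
#' @param prevention One of `"surveillance"`, `"mastectomy"`, `"oophorectomy"`,
#'   `"both"`, `"standard_care"`.
#' @param weight Proportion of the arm's cohort in `[0, 1]`.
#' @return A `subcohort` list.
#' @export
subcohort <- function(arm, label, test_result, carrier, prevention, weight) {
  arm <- match.arg(arm, c("testing", "no_testing"))
  test_result <- match.arg(test_result, c("positive", "negative", "untested"))
  prevention <- match.arg(prevention, c("surveillance", "mastectomy",
                                        "oophorectomy", "both", "standard_care"))
  if (prevention %in% c("mastectomy", "oophorectomy", "both") &&
      !(carrier && test_result == "positive")) {
    stop("prophylactic surgery is only modelled for women testing positive")
  }
  structure(list(arm = arm, label = label, test_result = test_result,
                 carrier = carrier, prevention = prevention, weight = weight),
            class = "subcohort")
}

# Model inputs -----------------------------------------------------------------

# Resolve a parameter, preferring a Monte Carlo draw vector when present.
pval <- function(params, draws, path) {
  if (!is.null(draws) && !is.null(draws[[path]])) draws[[path]] else
    get_parameter(params, path)
}

band_paths <- function(field) sprintf("probabilities.%s.bands[%d].p", field, 1:6)

# Assemble everything the engine needs for one subcohort: per-draw transition
# inputs, utility multipliers, state costs and one-time cycle-0 charges.
subcohort_inputs <- function(params, sub, draws = NULL) {
  n <- if (is.null(draws) || !length(draws)) 1L else max(lengths(draws))
  v <- function(x) rep_len(as.numeric(x), n)
  mat6 <- function(paths) {
    m <- matrix(0, n, 6)
    for (k in 1:6) m[, k] <- v(pval(params, draws, paths[k]))
    m
  }
  pr <- params$probabilities
  prev <- sub$prevention

  pbc <- switch(prev,
    mastectomy = matrix(v(pval(params, draws, "probabilities.well_to_bc_after_mastectomy")), n, 6),
    both       = matrix(v(pval(params, draws, "probabilities.well_to_bc_after_both")), n, 6),
    oophorectomy = mat6(band_paths("well_to_bc_after_oophorectomy")),
    if (sub$carrier) mat6(band_paths("well_to_bc_carrier")) else
                     mat6(band_paths("well_to_bc_noncarrier")))
  poc <- switch(prev,
    mastectomy = v(pval(params, draws, "probabilities.well_to_oc_after_mastectomy")),
    both       = v(pval(params, draws, "probabilities.well_to_oc_after_both")),
    oophorectomy = v(pval(params, draws, "probabilities.well_to_oc_after_oophorectomy")),
    if (sub$carrier) v(pval(params, draws, "probabilities.well_to_oc_carrier")) else
                     v(pval(params, draws, "probabilities.well_to_oc_noncarrier")))

  recur <- if (sub$carrier) v(pval(params, draws, "probabilities.recurrence_bc_carrier")) else
                            v(pval(params, draws, "probabilities.recurrence_bc_noncarrier"))
  pmet  <- v(pval(params, draws, "probabilities.bc_to_metastatic"))
  pbcoc <- v(pval(params, draws, "probabilities.bc_to_oc"))
  pdbc  <- v(pval(params, draws, "probabilities.bc_mortality"))

  as_conditional <- identical(params$options$tunnel_mortality, "conditional")
  sched_cond <- function(field) {
    cum <- matrix(0, n, 5)
    for (k in 1:5) cum[, k] <- v(pval(params, draws, sprintf("probabilities.%s.cum[%d]", field, k)))
    if (as_conditional) return(cum)          # table read as per-cycle values
    cum <- t(apply(cum, 1, cummax))          # sampling can break monotonicity
    if (n == 1) cum <- matrix(cum, 1, 5)
    prevc <- cbind(0, cum[, -5, drop = FALSE])
    cond <- (cum - prevc) / (1 - prevc)
    cond[!is.finite(cond)] <- 1
    cond
  }
  met_cond <- sched_cond("metastatic_death")
  oc_cond  <- sched_cond("oc_death")

  # share of incident breast cancers metastatic (late-stage) at diagnosis,
  # tied to the group's stage-at-diagnosis profile (see vignette)
  f_late <- if (identical(params$options$bc_stage_split, "registry")) {
    if (sub$test_result != "untested")
      v(pval(params, draws, "probabilities.bc_late_stage_tested")) else
      v(pval(params, draws, "probabilities.bc_late_stage_untested"))
  } else v(0)

  # age-band structure and background mortality (not sampled)
  ec <- params$economics
  ages <- ec$start_age + 0:(ec$horizon_years - 1)
  idx6  <- band_index(pr$well_to_bc_carrier, ages)
  idx12 <- band_index(pr$all_cause_mortality, ages)
  bg <- pr$all_cause_mortality$bands$p

  # utilities: multipliers relative to the age-declining baseline
  ut <- params$utilities
  m_hr <- v(pval(params, draws, "utilities.multiplier_high_risk"))
  # well multiplier assignment follows true carrier status (see vignette)
  opt_key <- if (sub$test_result == "negative") params$options$utility_negative
             else if (sub$test_result == "untested" && !sub$carrier)
               params$options$utility_untested_noncarrier
             else if (sub$test_result == "untested")
               params$options$utility_untested_carrier
             else "high_risk"
  m_well <- if (identical(opt_key, "population")) v(1) else
            if (identical(opt_key, "high_risk")) m_hr else v(as.numeric(opt_key))
  surg <- prev %in% c("mastectomy", "oophorectomy", "both")
  if (surg) {
    m_surg <- v(pval(params, draws, paste0("utilities.multiplier_", prev)))
    inc_surg <- switch(prev,
      mastectomy = v(pval(params, draws, "utilities.recovery_increment_mastectomy")),
      both       = v(pval(params, draws, "utilities.recovery_increment_both")),
      oophorectomy = (m_hr - m_surg) / 4)   # no printed increment: linear return
  } else {
    m_surg <- inc_surg <- NULL
  }

  cost_of <- function(path) v(pval(params, draws, path))
  sched_cost <- function(field) {
    m <- matrix(0, n, 5)
    for (k in 1:5) m[, k] <- cost_of(sprintf("costs.%s[%d]", field, k))
    m
  }
  bc_field <- if (sub$test_result == "positive" &&
                  identical(params$options$bc_cost_schedule_positives, "relative"))
    "bc_relative_yearly" else "bc_index_yearly"
  intensive <- (sub$test_result == "positive" && prev == "surveillance") ||
    (prev == "oophorectomy" &&
       identical(params$options$screening_after_oophorectomy, "intensive"))
  well_cost <- if (intensive) cost_of("costs.intensive_screening_annual") else
                              cost_of("costs.standard_care_annual")
  one_time <- v(0)
  if (sub$arm == "testing") {
    base_tc <- test_cost_per_woman(params$costs$cost_index_test,
                                   params$costs$cost_relative_test,
                                   params$costs$n_relatives_per_index)
    tc <- if (!is.null(draws) && !is.null(draws[["costs.test_cost_per_woman"]]))
      draws[["costs.test_cost_per_woman"]] else base_tc
    one_time <- one_time + v(tc)
  }
  if (surg) one_time <- one_time + cost_of(paste0("costs.surgery_", prev))

  list(n = n, sub = sub,
       pbc = pbc, poc = poc, recur = recur, pmet = pmet, pbcoc = pbcoc,
       pdbc = pdbc, met_cond = met_cond, oc_cond = oc_cond, f_late = f_late,
       idx6 = idx6, idx12 = idx12, bg = bg,
       baseline30 = v(pval(params, draws, "utilities.baseline_age30")),
       age_dec = v(ut$annual_age_decrement),
       m_well = m_well, m_hr = m_hr, m_surg = m_surg, inc_surg = inc_surg,
       surg = surg,
       m_bc = v(pval(params, draws, "utilities.multiplier_bc")),
       m_pbc = v(pval(params, draws, "utilities.multiplier_post_bc")),
       inc_bc = v(pval(params, draws, "utilities.recovery_increment_bc")),
       m_met = v(pval(params, draws, "utilities.multiplier_metastatic")),
       m_oc = v(pval(params, draws, "utilities.multiplier_oc")),
       m_poc = v(pval(params, draws, "utilities.multiplier_post_oc")),
       inc_oc = v(pval(params, draws, "utilities.recovery_increment_oc")),
       well_cost = well_cost, bc_cost = sched_cost(bc_field),
       met_cost = sched_cost("metastatic_yearly"),
       oc_cost = sched_cost("oc_yearly"),
       one_time = one_time)
}

# Well-state utility multiplier at cycle t (0-based): surgery decrement in the
# first year, printed linear recovery over years 2-5, high-risk level after.
well_multiplier <- function(inp, t) {
  if (!inp$surg) return(inp$m_well)
  if (t == 0) inp$m_surg
  else if (t <= 4) inp$m_surg + t * inp$inc_surg
  else inp$m_hr
}

# Per-state utility multipliers (n x 20) at cycle t.
state_multipliers <- function(inp, t) {
  n <- inp$n
  M <- matrix(0, n, .S)
  M[, .I$well] <- well_multiplier(inp, t)
  M[, .I$bc1] <- inp$m_bc
  for (k in 2:5) M[, .I$pbc[k - 1]] <- inp$m_bc + (k - 1) * inp$inc_bc
  M[, .I$pbcs] <- inp$m_pbc
  M[, .I$met] <- inp$m_met
  M[, .I$mets] <- inp$m_met
  M[, .I$oc1] <- inp$m_oc
  for (k in 2:5) M[, .I$poc[k - 1]] <- inp$m_oc + (k - 1) * inp$inc_oc
  M[, .I$pocs] <- inp$m_poc
  pmin(M, 1)
}

# Per-state annual costs (n x 20); steady post states carry the year-5 value.
state_costs <- function(inp) {
  n <- inp$n
  C <- matrix(0, n, .S)
  C[, .I$well] <- inp$well_cost
  C[, .I$bc1] <- inp$bc_cost[, 1]
  for (k in 2:5) C[, .I$pbc[k - 1]] <- inp$bc_cost[, k]
  C[, .I$pbcs] <- inp$bc_cost[, 5]
  for (k in 1:5) C[, .I$met[k]] <- inp$met_cost[, k]
  C[, .I$mets] <- inp$met_cost[, 5]
  C[, .I$oc1] <- inp$oc_cost[, 1]
  for (k in 2:5) C[, .I$poc[k - 1]] <- inp$oc_cost[, k]
  C[, .I$pocs] <- inp$oc_cost[, 5]
  C
}

check_outflows <- function(inp) {
  bad <- inp$recur + inp$pmet + inp$pbcoc + inp$pdbc > 1
  if (any(bad)) stop("breast-cancer state outflows sum to more than 1; refusing to renormalise")
  invisible(TRUE)
}

# Vectorised engine core -------------------------------------------------------

# Runs H cycles for one subcohort and n parameter draws simultaneously.
# Returns discounted totals; with keep_trace = TRUE (n must be 1) also the
# full occupancy trace and undiscounted per-cycle accruals.
run_model_core <- function(inp, econ, keep_trace = FALSE) {
  n <- inp$n
  H <- econ$horizon_years
  r <- econ$discount_rate
  if (keep_trace && n != 1) stop("trace output requires a single parameter draw")
  o <- matrix(0, n, .S)
  o[, .I$well] <- 1
  cost <- qaly <- ly <- numeric(n)
  clamp_count <- 0L
  C <- state_costs(inp)
  if (keep_trace) {
    occ <- matrix(NA_real_, H + 1, .S, dimnames = list(NULL, state_space()))
    occ[1, ] <- o
    acc <- matrix(NA_real_, H, 3, dimnames = list(NULL, c("cost", "utility", "ly")))
  }
  for (t in 0:(H - 1)) {
    # --- accrue on state membership at cycle start (no half-cycle correction)
    ubase <- inp$baseline30 - inp$age_dec * t
    M <- state_multipliers(inp, t)
    if (any(M < 0)) { clamp_count <- clamp_count + sum(M < 0); M[M < 0] <- 0 }
    u_t <- rowSums(o * (M * ubase))
    c_t <- rowSums(o * C)
    if (t == 0) c_t <- c_t + inp$one_time
    l_t <- 1 - o[, .I$dead]
    if (keep_trace) acc[t + 1, ] <- c(c_t, u_t, l_t)
    disc <- (1 + r)^(-t)
    cost <- cost + disc * c_t
    qaly <- qaly + disc * u_t
    ly   <- ly + disc * l_t

    # --- transition
    bg <- inp$bg[inp$idx12[t + 1]]
    sb <- 1 - bg
    pbc_t <- inp$pbc[, inp$idx6[t + 1]]
    poc_t <- inp$poc
    w <- o[, .I$well]
    bcf <- o[, 2:7, drop = FALSE]
    tot_bcf <- rowSums(bcf)
    new <- matrix(0, n, .S)
    dead_in <- w * bg

    new[, .I$well] <- w * sb * (1 - pbc_t) * (1 - poc_t)
    flow_bc1 <- w * sb * pbc_t * (1 - inp$f_late)
    flow_met1 <- w * sb * pbc_t * inp$f_late
    flow_oc1 <- w * sb * (1 - pbc_t) * poc_t

    adv <- sb * (1 - inp$recur - inp$pmet - inp$pbcoc - inp$pdbc)
    flow_bc1 <- flow_bc1 + tot_bcf * sb * inp$recur
    flow_met1 <- flow_met1 + tot_bcf * sb * inp$pmet
    flow_oc1 <- flow_oc1 + tot_bcf * sb * inp$pbcoc
    dead_in <- dead_in + tot_bcf * (bg + sb * inp$pdbc)
    new[, 3] <- o[, 2] * adv
    new[, 4] <- o[, 3] * adv
    new[, 5] <- o[, 4] * adv
    new[, 6] <- o[, 5] * adv
    new[, 7] <- (o[, 6] + o[, 7]) * adv
    new[, .I$bc1] <- flow_bc1
    new[, .I$met[1]] <- flow_met1

    for (k in 1:5) {
      d <- inp$met_cond[, k]
      st <- .I$met[1] - 1L + k
      dead_in <- dead_in + o[, st] * (bg + sb * d)
      new[, st + 1L] <- new[, st + 1L] + o[, st] * sb * (1 - d)
    }
    d5 <- inp$met_cond[, 5]
    dead_in <- dead_in + o[, .I$mets] * (bg + sb * d5)
    new[, .I$mets] <- new[, .I$mets] + o[, .I$mets] * sb * (1 - d5)

    for (k in 1:5) {
      e <- inp$oc_cond[, k]
      st <- .I$oc1 - 1L + k
      dead_in <- dead_in + o[, st] * (bg + sb * e)
      new[, st + 1L] <- new[, st + 1L] + o[, st] * sb * (1 - e)
    }
    new[, .I$oc1] <- flow_oc1
    dead_in <- dead_in + o[, .I$pocs] * bg
    new[, .I$pocs] <- new[, .I$pocs] + o[, .I$pocs] * sb
    new[, .I$dead] <- o[, .I$dead] + dead_in
    o <- new
    if (keep_trace) occ[t + 2, ] <- o
  }
  out <- list(cost = cost, qaly = qaly, ly = ly, clamp_count = clamp_count)
  if (keep_trace) { out$occupancy <- occ; out$accruals <- acc }
  out
}

# Transition-matrix path -------------------------------------------------------

#' Build the one-cycle transition matrix for a subcohort
#'
#' Row-stochastic 20 x 20 matrix over the expanded state space at a given
#' cycle. Background (all-cause) mortality is applied first in every alive
#' state; survivors then face the cause-specific transition probabilities, so
#' `P(death) = bg + (1 - bg) * p_cause` and every other transition is scaled
#' by `(1 - bg)`. Forbidden transitions (ovarian cancer to breast cancer,
#' anything out of death) are exactly zero. Competing cause-specific outflows
#' summing above 1 raise an error naming the state; nothing is silently
#' renormalised.
#'
#' @param params A `parameter_set`.
#' @param sub A [subcohort()].
#' @param cycle Cycle index in `0..horizon-1`; age is `start_age + cycle`.
#' @return A 20 x 20 matrix with dimnames from [state_space()].
#' @export
build_transition_matrix <- function(params, sub, cycle) {
  ec <- params$economics
  if (cycle < 0 || cycle >= ec$horizon_years) stop("cycle out of 0..horizon-1")
  inp <- subcohort_inputs(params, sub)
  check_outflows(inp)
  sn <- state_space()
  P <- matrix(0, .S, .S, dimnames = list(sn, sn))
  bg <- inp$bg[inp$idx12[cycle + 1]]
  sb <- 1 - bg
  pbc <- inp$pbc[1, inp$idx6[cycle + 1]]
  poc <- inp$poc[1]
  f <- inp$f_late[1]
  P[1, .I$bc1] <- sb * pbc * (1 - f)
  P[1, .I$met[1]] <- sb * pbc * f
  P[1, .I$oc1] <- sb * (1 - pbc) * poc
  P[1, .I$dead] <- bg
  P[1, 1] <- sb * (1 - pbc) * (1 - poc)
  spec_sum <- inp$recur + inp$pmet + inp$pbcoc + inp$pdbc
  if (spec_sum > 1) {
    stop(sprintf("breast-cancer state outflow > 1 at cycle %d", cycle))
  }
  succ_bc <- c(3:7, 7)                     # tunnel successor for states 2..7
  for (i in 2:7) {
    P[i, .I$bc1] <- sb * inp$recur
    P[i, .I$met[1]] <- sb * inp$pmet
    P[i, .I$oc1] <- sb * inp$pbcoc
    P[i, .I$dead] <- bg + sb * inp$pdbc
    j <- succ_bc[i - 1]
    P[i, j] <- P[i, j] + sb * (1 - spec_sum)
  }
  for (k in 1:5) {
    i <- .I$met[1] - 1L + k
    d <- inp$met_cond[1, k]
    P[i, .I$dead] <- bg + sb * d
    P[i, i + 1L] <- sb * (1 - d)
  }
  d5 <- inp$met_cond[1, 5]
  P[.I$mets, .I$dead] <- bg + sb * d5
  P[.I$mets, .I$mets] <- sb * (1 - d5)
  for (k in 1:5) {
    i <- .I$oc1 - 1L + k
    e <- inp$oc_cond[1, k]
    P[i, .I$dead] <- bg + sb * e
    P[i, i + 1L] <- sb * (1 - e)
  }
  P[.I$pocs, .I$dead] <- bg
  P[.I$pocs, .I$pocs] <- sb
  P[.I$dead, .I$dead] <- 1
  P
}

#' Run the cohort trace for one subcohort
#'
#' Starts the whole subcohort in `well` and applies the cycle-specific
#' transition matrices for the full horizon. Also records undiscounted
#' per-cycle cost, utility and life-year accruals (state membership valued at
#' cycle start; one-time test/surgery charges at cycle 0).
#'
#' @param params A `parameter_set`.
#' @param sub A [subcohort()].
#' @return A `cohort_trace`: list with `occupancy` (`horizon + 1` rows by 20
#'   states) and `accruals` (`horizon` rows: cost, utility, ly).
#' @export
run_trace <- function(params, sub) {
  ec <- params$economics
  inp <- subcohort_inputs(params, sub)
  check_outflows(inp)
  H <- ec$horizon_years
  occ <- matrix(NA_real_, H + 1, .S, dimnames = list(NULL, state_space()))
  occ[1, ] <- c(1, rep(0, .S - 1))
  acc <- matrix(NA_real_, H, 3, dimnames = list(NULL, c("cost", "utility", "ly")))
  C <- state_costs(inp)[1, ]
  for (t in 0:(H - 1)) {
    ubase <- inp$baseline30[1] - inp$age_dec[1] * t
    M <- pmax(state_multipliers(inp, t)[1, ], 0)
    acc[t + 1, "utility"] <- sum(occ[t + 1, ] * M * ubase)
    acc[t + 1, "cost"] <- sum(occ[t + 1, ] * C) + if (t == 0) inp$one_time[1] else 0
    acc[t + 1, "ly"] <- 1 - occ[t + 1, .I$dead]
    P <- tryCatch(build_transition_matrix(params, sub, t),
                  error = function(e) stop("cycle ", t, ": ", conditionMessage(e),
                                           call. = FALSE))
    occ[t + 2, ] <- occ[t + 1, ] %*% P
  }
  structure(list(occupancy = occ, accruals = acc, sub = sub), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$accruals)
  cat(sprintf("Cohort trace: %s / %s, %d cycles\n", x$sub$arm, x$sub$label, H))
  cat(sprintf("  dead at end of horizon: %.4f\n", x$occupancy[H + 1, "death"]))
  invisible(x)
}

#' Accumulate discounted totals over a cohort trace
#'
#' Discounts the per-cycle accruals of [run_trace()] at the configured annual
#' rate: accrual in cycle `t` is weighted by `(1 + r)^(-t)`.
#'
#' @param trace A `cohort_trace`.
#' @param params The `parameter_set` the trace was run with.
#' @return Named numeric vector with `cost`, `qaly`, `ly`.
#' @export
accumulate <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"))
  r <- params$economics$discount_rate
  H <- nrow(trace$accruals)
  disc <- (1 + r)^(-(0:(H - 1)))
  c(cost = sum(disc * trace$accruals[, "cost"]),
    qaly = sum(disc * trace$accruals[, "utility"]),
    ly = sum(disc * trace$accruals[, "ly"]))
}
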