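arms_subs <- c(expand_arm(base_params, "testing"),
               expand_arm(base_params, "no_testing"))

test_that("every transition matrix is row-stochastic with legal structure", {
  sn <- state_space()
  for (sub in arms_subs) {
    for (cyc in c(0, 7, 24, 42, 55, 69)) {
      P <- build_transition_matrix(base_params, sub, cyc)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
      expect_true(all(P >= 0 & P <= 1))
      # death absorbing; nothing leaves it
      expect_identical(unname(P["death", "death"]), 1)
      expect_true(all(P["death", sn != "death"] == 0))
      # ovarian cancer never transitions to breast cancer
      oc_states <- grep("oc", sn, value = TRUE)
      bc_states <- c("bc_y1", grep("^post_bc|^met", sn, value = TRUE))
      expect_true(all(P[oc_states, bc_states] == 0))
      # tunnel years advance to exactly one successor (no advancement at the
      # terminal mortality band, where background death is certain)
      if (cyc < 55) expect_gt(P["post_bc_y2", "post_bc_y3"], 0)
      expect_identical(unname(P["post_bc_y2", "post_bc_y4"]), 0)
    }
  }
  expect_error(build_transition_matrix(base_params, arms_subs[[1]], 70), "cycle")
})

test_that("well-row probabilities compose the published inputs with background mortality applied first", {
  sub <- expand_arm(base_params, "no_testing")[[2]]   # untested non-carrier
  P <- build_transition_matrix(base_params, sub, 0)   # age 30
  bg <- 0.004
  f_late <- 0.5208
  expect_equal(unname(P["well", "bc_y1"]), (1 - bg) * 0.0011 * (1 - f_late))
  expect_equal(unname(P["well", "met_y1"]), (1 - bg) * 0.0011 * f_late)
  expect_equal(unname(P["well", "oc_y1"]),
               (1 - bg) * (1 - 0.0011) * 8.728e-05)
  expect_equal(unname(P["well", "death"]), bg)
  # carriers with both surgeries: no breast or ovarian cancer risk
  both <- expand_arm(base_params, "testing")[[5]]
  Pb <- build_transition_matrix(base_params, both, 0)
  expect_identical(unname(Pb["well", "bc_y1"]), 0)
  expect_identical(unname(Pb["well", "oc_y1"]), 0)
  expect_equal(unname(Pb["well", "well"]), 1 - bg)
})

test_that("competing outflows above 1 raise rather than renormalise", {
  bad <- set_parameter(base_params, "probabilities.recurrence_bc_carrier", 0.95)
  bad <- set_parameter(bad, "probabilities.bc_mortality", 0.10)
  sub <- expand_arm(base_params, "no_testing")[[1]]
  expect_error(build_transition_matrix(bad, sub, 3), "outflow")
  expect_error(evaluate_strategy(bad, "no_testing"), "renormalise")
})

test_that("cohort traces conserve mass and accumulate consistently across both engine paths", {
  for (sub in arms_subs) {
    tr <- run_trace(base_params, sub)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
    expect_identical(unname(tr$occupancy[1, "well"]), 1)
    acc <- accumulate(tr, base_params)
    core <- hboccea:::run_model_core(
      hboccea:::subcohort_inputs(base_params, sub), base_params$economics)
    expect_equal(unname(acc["cost"]), core$cost, tolerance = 1e-9)
    expect_equal(unname(acc["qaly"]), core$qaly, tolerance = 1e-12)
    expect_equal(unname(acc["ly"]), core$ly, tolerance = 1e-12)
    expect_identical(core$clamp_count, 0L)      # no negative-utility clamping
    expect_lt(core$qaly, core$ly)               # utilities never exceed 1
  }
})

test_that("degenerate dynamics behave as expected", {
  # no mortality, no incidence: the cohort never leaves well
  p0 <- flat_mortality_params(base_params, 0)
  for (k in 1:6) {
    p0 <- set_parameter(p0, sprintf("probabilities.well_to_bc_noncarrier.bands[%d].p", k), 0)
  }
  p0 <- set_parameter(p0, "probabilities.well_to_oc_noncarrier", 0)
  sub <- expand_arm(p0, "no_testing")[[2]]
  tr <- run_trace(p0, sub)
  expect_true(all(tr$occupancy[, "well"] == 1))
  # certain death: everyone dead after one cycle
  p1 <- flat_mortality_params(base_params, 1)
  tr1 <- run_trace(p1, sub)
  expect_identical(unname(tr1$occupancy[2, "death"]), 1)
  # carriers under surveillance die faster than non-carriers
  subs <- expand_arm(base_params, "no_testing")
  trc <- run_trace(base_params, subs[[1]])
  trn <- run_trace(base_params, subs[[2]])
  expect_gt(trc$occupancy[71, "death"], trn$occupancy[71, "death"])
})

test_that("two-state miniature matches the closed-form discounted life years", {
  p <- flat_mortality_params(base_params, 0.03)
  for (k in 1:6) {
    p <- set_parameter(p, sprintf("probabilities.well_to_bc_noncarrier.bands[%d].p", k), 0)
  }
  p <- set_parameter(p, "probabilities.well_to_oc_noncarrier", 0)
  sub <- expand_arm(p, "no_testing")[[2]]
  for (r in c(0, 0.05, 0.10)) {
    pr <- set_parameter(p, "economics.discount_rate", r)
    acc <- accumulate(run_trace(pr, sub), pr)
    expect_equal(unname(acc["ly"]), closed_form_disc_ly(0.03, r, 70),
                 tolerance = 1e-9)
  }
  # three states: well -> ovarian cancer at a constant rate, cancer itself
  # non-lethal, so survival (and discounted LY) still follows the two-state
  # closed form while occupancy redistributes
  p3 <- set_parameter(p, "probabilities.well_to_oc_noncarrier", 0.1)
  for (k in 1:5) p3 <- set_parameter(p3, sprintf("probabilities.oc_death.cum[%d]", k), 0)
  acc3 <- accumulate(run_trace(p3, sub), p3)
  expect_equal(unname(acc3["ly"]), closed_form_disc_ly(0.03, 0.05, 70),
               tolerance = 1e-9)
  tr3 <- run_trace(p3, sub)
  expect_gt(tr3$occupancy[40, "post_oc"], 0.2)
})

test_that("discounted totals decrease as the discount rate rises", {
  prev <- NULL
  for (r in c(0, 0.05, 0.10)) {
    p <- set_parameter(base_params, "economics.discount_rate", r)
    res <- evaluate_strategy(p, "no_testing")
    if (!is.null(prev)) {
      expect_lt(res$cost, prev$cost)
      expect_lt(res$qaly, prev$qaly)
      expect_lt(res$ly, prev$ly)
    }
    prev <- res
  }
})

test_that("utility accrual follows the multiplier schedule", {
  # cycle-0 well utility of a carrier under surveillance: baseline x high-risk
  inp <- hboccea:::subcohort_inputs(base_params,
                                    expand_arm(base_params, "testing")[[2]])
  M <- hboccea:::state_multipliers(inp, 0)
  expect_equal(M[1, 1] * inp$baseline30, 0.920 * 0.92)
  # mastectomy recovery: 0.88, then +0.008/yr, back at the high-risk level
  inpm <- hboccea:::subcohort_inputs(base_params,
                                     expand_arm(base_params, "testing")[[3]])
  m <- vapply(0:6, function(t) hboccea:::well_multiplier(inpm, t), 0)
  expect_equal(m, c(0.88, 0.888, 0.896, 0.904, 0.912, 0.92, 0.92))
  # ovarian-cancer tunnel recovers by +0.111/yr toward the post-cancer level
  expect_equal(M[1, 14:19], c(0.34, 0.451, 0.562, 0.673, 0.784, 0.83))
  # discount factors
  r <- base_params$economics$discount_rate
  expect_identical((1 + r)^0, 1)
  expect_equal(1 / (1 + r), 0.952381, tolerance = 1e-6)
})

test_that("a cohort parked in the ovarian-cancer state accrues its published year-1 cost", {
  inp <- hboccea:::subcohort_inputs(base_params,
                                    expand_arm(base_params, "no_testing")[[1]])
  C <- hboccea:::state_costs(inp)
  expect_identical(C[1, 14], 14224.92)
  expect_identical(C[1, 19], 240.68)    # steady post-OC follow-up cost
  expect_identical(C[1, 13], 15914.02)  # steady metastatic cost
  expect_identical(C[1, 7], 719.03)     # steady post-BC cost
})
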