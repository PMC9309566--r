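test_that("cumulative-to-conditional conversion round-trips exactly", {
  # frozen expectations computed with the re-accumulation oracle
  mets <- cumulative_to_conditional(c(0.37, 0.61, 0.76, 0.85, 0.90))
  expect_equal(mets$cond, c(0.37, 0.380952380952381, 0.384615384615385,
                            0.375, 1 / 3), tolerance = 1e-12)
  expect_equal(reaccumulate(mets$cond), c(0.37, 0.61, 0.76, 0.85, 0.90),
               tolerance = 1e-12)
  oc <- cumulative_to_conditional(c(0.10, 0.18, 0.25, 0.32, 0.39))
  expect_equal(oc$cond[2], 0.08 / 0.90, tolerance = 1e-12)
  expect_equal(reaccumulate(oc$cond), c(0.10, 0.18, 0.25, 0.32, 0.39),
               tolerance = 1e-12)
  expect_equal(cumulative_to_conditional(rep(0, 5))$cond, rep(0, 5))

  # property: round trip holds for arbitrary valid monotone schedules
  set.seed(1)
  for (i in 1:50) {
    cum <- sort(runif(5, 0, 0.98))
    expect_equal(reaccumulate(cumulative_to_conditional(cum)$cond), cum,
                 tolerance = 1e-12)
  }
  expect_error(cumulative_schedule(c(0.3, 0.2, 0.4, 0.5, 0.6)), "year 2")
  expect_warning(cumulative_to_conditional(c(0.5, 1, 1, 1, 1)), "set to 1")
})

test_that("per-woman test cost averages index and relative costs", {
  expect_identical(test_cost_per_woman(1800, 235, 2), 1135)
  expect_identical(test_cost_per_woman(1800, 235, 1), 2035)
  expect_identical(test_cost_per_woman(1800, 235, 4), 685)
  expect_error(test_cost_per_woman(1800, 235, 0), "n_relatives")
  # strictly decreasing in the number of relatives, converging to the
  # relative-test cost
  costs <- test_cost_per_woman(1800, 235, 1:50)
  expect_true(all(diff(costs) < 0))
  expect_lt(test_cost_per_woman(1800, 235, 1e7) - 235, 1e-3)
})

test_that("method-of-moments distribution fits reproduce their moments", {
  b <- fit_distribution(0.5, sd = 0.1, family = "beta")
  expect_equal(b$shape1, 12)
  expect_equal(b$shape2, 12)
  g <- fit_distribution(1135, sd = 454, family = "gamma")
  expect_equal(g$shape, 6.25)
  expect_equal(g$scale, 181.6)
  r <- fit_distribution(0.03, lo = 0.02, hi = 0.04, family = "beta")
  expect_equal(r$sd, 0.02 / 3.92)
  # analytic mean identity and Monte Carlo mean/sd at n = 1e6
  set.seed(42)
  for (spec in list(b, g, r)) {
    if (spec$family == "beta") {
      expect_equal(spec$shape1 / (spec$shape1 + spec$shape2), spec$mean,
                   tolerance = 1e-9)
    } else {
      expect_equal(spec$shape * spec$scale, spec$mean, tolerance = 1e-9)
    }
    x <- draw_distribution(spec, 1e6)
    expect_lt(abs(mean(x) - spec$mean), 3 * spec$sd / sqrt(1e6))
    expect_lt(abs(sd(x) / spec$sd - 1), 0.02)
  }
  expect_warning(fit_distribution(0.9, sd = 0.5, family = "beta"), "shrunk")
  expect_error(fit_distribution(1.2, sd = 0.1, family = "beta"), "mean in")
  expect_error(fit_distribution(-3, sd = 1, family = "gamma"), "mean > 0")
})

test_that("shipped base case carries the published table values", {
  p <- base_params
  expect_identical(p$probabilities$p_positive_test, 0.18)
  expect_identical(p$probabilities$uptake_mastectomy, 0.03)
  expect_identical(p$probabilities$uptake_oophorectomy, 0.12)
  expect_identical(p$probabilities$uptake_both, 0.12)
  expect_equal(p$probabilities$well_to_bc_carrier$bands$p,
               c(0.012, 0.016, 0.022, 0.027, 0.029, 0.037))
  expect_equal(p$probabilities$well_to_bc_noncarrier$bands$p,
               c(0.0011, 0.0017, 0.002, 0.004, 0.006, 0.008))
  expect_identical(p$probabilities$well_to_oc_carrier, 0.013)
  expect_identical(p$probabilities$well_to_oc_noncarrier, 8.728e-05)
  expect_equal(p$probabilities$metastatic_death$cum, c(0.37, 0.61, 0.76, 0.85, 0.90))
  expect_equal(p$probabilities$oc_death$cum, c(0.10, 0.18, 0.25, 0.32, 0.39))
  expect_equal(p$probabilities$all_cause_mortality$bands$p[c(1, 6, 12)],
               c(0.004, 0.028, 1))
  expect_identical(p$utilities$baseline_age30, 0.92)
  expect_identical(p$utilities$multiplier_high_risk, 0.92)
  expect_identical(p$utilities$multiplier_oc, 0.34)
  expect_equal(p$costs$bc_index_yearly, c(17813.11, 958.95, 719.03, 719.03, 719.03))
  expect_equal(p$costs$metastatic_yearly,
               c(18392.61, 17285.58, 14949.91, 15914.02, 15914.02))
  expect_equal(p$costs$oc_yearly, c(14224.92, 1654.11, 6487.23, 240.68, 240.68))
  expect_identical(p$costs$intensive_screening_annual, 428.85)
  expect_identical(p$costs$surgery_both, 4105.26)
  expect_identical(p$economics$discount_rate, 0.05)
  expect_identical(p$economics$horizon_years, 70L)
})

test_that("validation returns findings, not exceptions", {
  expect_identical(nrow(validate_parameters(base_params)), 0L)
  bad <- set_parameter(base_params, "probabilities.uptake_mastectomy", 0.5)
  bad <- set_parameter(bad, "probabilities.uptake_oophorectomy", 0.4)
  bad <- set_parameter(bad, "probabilities.uptake_both", 0.3)
  f <- validate_parameters(bad)
  expect_true(any(grepl("uptake sum > 1", f$message)))
  f2 <- validate_parameters(set_parameter(base_params, "economics.discount_rate", -0.01))
  expect_true(any(grepl("discount_rate < 0", f2$message)))
  f3 <- validate_parameters(set_parameter(base_params, "probabilities.bc_mortality", 1.4))
  expect_true(any(f3$path == "probabilities.bc_mortality"))
})

test_that("dotted-path access reads and writes any parameter", {
  expect_identical(get_parameter(base_params, "economics.discount_rate"), 0.05)
  expect_identical(get_parameter(base_params, "costs.bc_index_yearly[2]"), 958.95)
  expect_identical(
    get_parameter(base_params, "probabilities.well_to_bc_carrier.bands[3].p"), 0.022)
  p2 <- set_parameter(base_params, "probabilities.well_to_bc_carrier.bands[3].p", 0.5)
  expect_identical(
    get_parameter(p2, "probabilities.well_to_bc_carrier.bands[3].p"), 0.5)
  expect_identical(  # base case untouched
    get_parameter(base_params, "probabilities.well_to_bc_carrier.bands[3].p"), 0.022)
  p3 <- set_parameter(base_params, "costs.oc_yearly", rep(1, 5))
  expect_equal(get_parameter(p3, "costs.oc_yearly"), rep(1, 5))
  expect_error(get_parameter(base_params, "no.such.path"), "unknown parameter path")
  expect_error(set_parameter(base_params, "costs.nope", 1), "unknown parameter path")
})

test_that("age-banded rates enforce contiguity and support lookup", {
  abr <- age_banded_rate(c(30, 35), c(34, Inf), c(0.1, 0.2))
  expect_identical(rate_lookup(abr, c(30, 34, 35, 90)), c(0.1, 0.1, 0.2, 0.2))
  expect_error(age_banded_rate(c(30, 36), c(34, Inf), c(0.1, 0.2)), "contiguous")
  expect_error(age_banded_rate(30, Inf, 1.2), "\\[0, 1\\]")
  expect_error(rate_lookup(abr, 20), "below first band")
})

test_that("PSA registry covers printed uncertainty plus 40%-sd costs", {
  tab <- psa_parameter_table(base_params)
  expect_true(all(tab$family %in% c("beta", "gamma")))
  expect_true(all(tab$sd > 0))
  # every cost row uses the 40% rule; the derived unit test cost is included
  costs <- tab[tab$family == "gamma", ]
  expect_equal(costs$sd, 0.4 * costs$mean)
  expect_true("costs.test_cost_per_woman" %in% tab$path)
  expect_identical(tab$mean[tab$path == "costs.test_cost_per_woman"], 1135)
  # fixed quantities stay out: positivity rate and background mortality
  expect_false(any(grepl("p_positive_test|all_cause_mortality", tab$path)))
  # n_relatives scenario edits propagate into the sampled test-cost mean
  p1 <- set_parameter(base_params, "costs.n_relatives_per_index", 1)
  tab1 <- psa_parameter_table(p1)
  expect_identical(tab1$mean[tab1$path == "costs.test_cost_per_woman"], 2035)
})
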