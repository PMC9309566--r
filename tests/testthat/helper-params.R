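# Shared fixtures: the shipped base case is loaded once per test run.
base_params <- default_parameters()

# Re-accumulate a conditional schedule over a unit cohort (independent oracle
# for the cumulative -> conditional conversion).
reaccumulate <- function(cond) {
  alive <- 1
  cum <- numeric(length(cond))
  dead <- 0
  for (t in seq_along(cond)) {
    dead <- dead + alive * cond[t]
    alive <- alive * (1 - cond[t])
    cum[t] <- dead
  }
  cum
}

# Closed-form discounted life years for a cohort facing a constant annual
# death probability p over H cycles at discount rate r (geometric series).
closed_form_disc_ly <- function(p, r, H) {
  q <- (1 - p) / (1 + r)
  sum(q^(0:(H - 1)))
}

# A parameter set with a constant all-cause mortality in every band.
flat_mortality_params <- function(params, p) {
  for (k in 1:12) {
    params <- set_parameter(
      params, sprintf("probabilities.all_cause_mortality.bands[%d].p", k), p)
  }
  params
}
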