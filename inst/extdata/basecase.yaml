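# Base-case inputs: annual probabilities, health-state utilities (relative to
# an age-declining baseline) and 2021 SUS reimbursement costs in R$.
# Uncertain quantities carry either a 95% interval (lo/hi) or an sd; costs use
# a 40% sd assumption in the probabilistic analysis.

economics:
  discount_rate: 0.05
  horizon_years: 70
  start_age: 30
  cycle_length: 1

probabilities:
  p_positive_test: 0.18
  uptake_mastectomy: {value: 0.03, lo: 0.02, hi: 0.04}
  uptake_oophorectomy: {value: 0.12, lo: 0.10, hi: 0.14}
  uptake_both: {value: 0.12, lo: 0.09, hi: 0.17}
  well_to_bc_carrier:
    bands:
      - {age_lo: 30, age_hi: 34, p: 0.012, lo: 0.010, hi: 0.013}
      - {age_lo: 35, age_hi: 39, p: 0.016, lo: 0.014, hi: 0.017}
      - {age_lo: 40, age_hi: 44, p: 0.022, lo: 0.020, hi: 0.024}
      - {age_lo: 45, age_hi: 49, p: 0.027, lo: 0.025, hi: 0.029}
      - {age_lo: 50, age_hi: 54, p: 0.029, lo: 0.027, hi: 0.031}
      - {age_lo: 55, age_hi: null, p: 0.037, lo: 0.033, hi: 0.040}
  well_to_bc_noncarrier:
    bands:
      - {age_lo: 30, age_hi: 34, p: 0.0011, sd: 0.0001}
      - {age_lo: 35, age_hi: 39, p: 0.0017, sd: 0.0001}
      - {age_lo: 40, age_hi: 44, p: 0.002,  sd: 0.0002}
      - {age_lo: 45, age_hi: 49, p: 0.004,  sd: 0.0004}
      - {age_lo: 50, age_hi: 54, p: 0.006,  sd: 0.0006}
      - {age_lo: 55, age_hi: null, p: 0.008, sd: 0.0008}
  # Breast cancer risk after risk-reducing surgery. After oophorectomy the
  # risk is assumed equal to that of an unoperated carrier except in the
  # first band (registry estimate); after mastectomy or both surgeries no
  # cases were observed.
  well_to_bc_after_mastectomy: 0
  well_to_bc_after_both: 0
  well_to_bc_after_oophorectomy:
    bands:
      - {age_lo: 30, age_hi: 34, p: 0.014, lo: 0.010, hi: 0.013}
      - {age_lo: 35, age_hi: 39, p: 0.016, lo: 0.014, hi: 0.017}
      - {age_lo: 40, age_hi: 44, p: 0.022, lo: 0.020, hi: 0.024}
      - {age_lo: 45, age_hi: 49, p: 0.027, lo: 0.025, hi: 0.029}
      - {age_lo: 50, age_hi: 54, p: 0.029, lo: 0.027, hi: 0.031}
      - {age_lo: 55, age_hi: null, p: 0.037, lo: 0.033, hi: 0.040}
  well_to_oc_carrier: {value: 0.013, sd: 0.052}
  well_to_oc_noncarrier: 0.00008728
  well_to_oc_after_mastectomy: 0
  well_to_oc_after_oophorectomy: {value: 0.01, lo: 0.0004, hi: 0.32}
  well_to_oc_after_both: 0
  all_cause_mortality:
    bands:
      - {age_lo: 30, age_hi: 34, p: 0.004}
      - {age_lo: 35, age_hi: 39, p: 0.006}
      - {age_lo: 40, age_hi: 44, p: 0.009}
      - {age_lo: 45, age_hi: 49, p: 0.013}
      - {age_lo: 50, age_hi: 54, p: 0.019}
      - {age_lo: 55, age_hi: 59, p: 0.028}
      - {age_lo: 60, age_hi: 64, p: 0.043}
      - {age_lo: 65, age_hi: 69, p: 0.065}
      - {age_lo: 70, age_hi: 74, p: 0.1}
      - {age_lo: 75, age_hi: 79, p: 0.16}
      - {age_lo: 80, age_hi: 84, p: 0.25}
      - {age_lo: 85, age_hi: null, p: 1}
  # stage profile at diagnosis: share of incident breast cancers that present
  # metastatic (stage III/IV), by whether the woman was tested before diagnosis
  bc_late_stage_untested: 0.5208
  bc_late_stage_tested: 0.4133
  recurrence_bc_carrier: {value: 0.069, lo: 0.054, hi: 0.091}
  recurrence_bc_noncarrier: {value: 0.003, sd: 0.001}
  bc_mortality: {value: 0.006, sd: 0.004}
  bc_to_metastatic: {value: 0.0134, lo: 0.0097, hi: 0.01737}
  bc_to_oc: {value: 0.007, lo: 0.004, hi: 0.010}
  metastatic_death:
    cum: [0.37, 0.61, 0.76, 0.85, 0.90]
    lo:  [0.31, 0.53, 0.68, 0.78, 0.85]
    hi:  [0.48, 0.73, 0.86, 0.92, 0.96]
  oc_death:
    cum: [0.10, 0.18, 0.25, 0.32, 0.39]
    sd:  [0.04, 0.06, 0.07, 0.08, 0.08]

utilities:
  baseline_age30: {value: 0.920, sd: 0.0072}
  annual_age_decrement: 0.00029
  multiplier_high_risk: 0.92
  multiplier_mastectomy: {value: 0.88, sd: 0.22}
  multiplier_oophorectomy: {value: 0.95, sd: 0.10}
  multiplier_both: {value: 0.83, sd: 0.10}
  recovery_increment_mastectomy: {value: 0.008, sd: 0.001}
  recovery_increment_both: {value: 0.02, sd: 0.011}
  multiplier_bc: {value: 0.77, sd: 0.18}
  multiplier_post_bc: {value: 0.79, sd: 0.18}
  recovery_increment_bc: {value: 0.0021, sd: 0.0007}
  multiplier_metastatic: {value: 0.64, sd: 0.12}
  multiplier_oc: {value: 0.34, sd: 0.30}
  multiplier_post_oc: {value: 0.83, sd: 0.25}
  recovery_increment_oc: {value: 0.111, sd: 0.022}

costs:
  cost_index_test: 1800
  cost_relative_test: 235
  n_relatives_per_index: 2
  intensive_screening_annual: 428.85
  standard_care_annual: 55.00
  surgery_mastectomy: 3484.26
  surgery_oophorectomy: 621.00
  surgery_both: 4105.26
  bc_index_yearly:     [17813.11, 958.95, 719.03, 719.03, 719.03]
  bc_relative_yearly:  [16540.09, 934.27, 719.03, 719.03, 719.03]
  metastatic_yearly:   [18392.61, 17285.58, 14949.91, 15914.02, 15914.02]
  oc_yearly:           [14224.92, 1654.11, 6487.23, 240.68, 240.68]
  psa_cost_sd_fraction: 0.40

# Structural choices the source model leaves open; see the methods vignette.
options:
  tunnel_mortality: conditional            # cumulative | conditional
  bc_stage_split: registry                 # none | registry
  utility_untested_carrier: high_risk      # high_risk | population
  utility_untested_noncarrier: population
  utility_negative: population
  screening_after_oophorectomy: intensive  # breast tissue still at risk
  bc_cost_schedule_positives: relative     # earlier-stage diagnosis after testing
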