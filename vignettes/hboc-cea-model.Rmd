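---
title: "A Markov cohort model for BRCA1/2 testing and prevention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for BRCA1/2 testing and prevention: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hboccea)
```

## The decision problem

Women with a strong family history of breast/ovarian cancer can be offered
BRCA1/2 genetic counselling and testing. A positive result opens
risk-reducing options — intensified surveillance, bilateral mastectomy,
salpingo-oophorectomy, or both surgeries — while a negative result returns
the woman to general-population screening. The model asks whether offering
the test (plus downstream prevention) is cost-effective for Brazil's public
payer compared with offering nobody the test, for a cohort of healthy
30-year-old women who meet clinical testing criteria.

## Model structure

The cohort moves in 1-year cycles over 70 years through *well*,
*non-metastatic breast cancer* (BC), *metastatic breast cancer*, *ovarian
cancer* (OC), *post-BC*, *post-OC* and *death*. Post-cancer follow-up years
2–5 and metastatic years 1–5 are tunnel states, so year-specific treatment
costs, utilities and mortality apply; from year 6 a steady post-cancer (or
metastatic) state holds the year-3..5 follow-up cost and the year-5
mortality where applicable. Contralateral breast cancer returns the woman
to the first BC year (and re-charges first-year treatment); OC never
transitions to BC. Death is absorbing.

Each strategy arm is a weighted mixture of homogeneous subcohorts (test
result x carrier status x prevention choice); weights come from the test
positivity rate (0.18) and the surgery uptake multinomial (0.03
mastectomy / 0.12 oophorectomy / 0.12 both / residual surveillance).
Strategy totals are weight-weighted sums, so the engine runs each subcohort
independently — which is also what makes the probabilistic analysis
vectorisable across parameter draws.

### Competing risks within a cycle

Background (all-cause) mortality is applied first in every alive state;
survivors then face the cause-specific probabilities, e.g. in the well
state `P(death) = bg`, `P(BC) = (1-bg) p_bc`,
`P(OC) = (1-bg)(1-p_bc) p_oc`. Two reasons over a plain additive row:
the life table's terminal band (85+) carries probability 1, which would
push additive outflows above 1 in every state, and the probabilistic
analysis draws heavily skewed beta variates for the ovarian-cancer risks
whose additive sum can exceed 1. The sequential composition is valid for
any probability draws and differs from the additive one by under 1% at the
ages that matter. Cause-specific outflows are still checked and an error is
raised — never a silent renormalisation — if they alone sum above 1.

Cancer-specific mortality is taken as cause-specific (it was derived from
cancer-cohort survival curves), so background mortality applies on top of
it inside cancer states, through the same composition.

### Two engine paths

`build_transition_matrix()`/`run_trace()` expose the explicit row-stochastic
matrices and the full occupancy trace for inspection, export and invariant
testing. `run_model_core()` (internal) evaluates the same recursion with
every parameter a vector across Monte Carlo draws, which is what makes a
10,000-draw PSA run in seconds. Their agreement on the base case is
asserted in the test suite to 1e-9, so the fast path is always checked
against the auditable one.

## Interpretation choices behind the shipped configuration

Several mechanics of this kind of decision model are conventions rather
than published facts, and the configuration makes each one an explicit,
overridable option. Three deserve explanation; all three defaults were
selected for consistency with the reference results this model
re-implements (external validation), and the alternatives remain available.

**Five-year mortality schedules (`options.tunnel_mortality`).** The
metastatic-BC and OC death inputs are monotone year-1..5 series of
Kaplan–Meier origin. Read as cumulative probabilities they should be
converted to per-cycle conditional values — `cumulative_to_conditional()`
implements exactly that, with a round-trip identity tested to 1e-12.
Decision-tree software, however, consumes per-cycle values, and series like
these are commonly entered directly as such. The default (`"conditional"`)
reads the table per-cycle, which implies near-complete 5-year metastatic
fatality; `"cumulative"` applies the conversion and yields a much milder
disease course. Only the former reproduces the reference incremental
results; the difference is a factor of ~3 in the ICER.

**Stage at diagnosis (`options.bc_stage_split`).** Surveillance shifts
breast-cancer diagnosis toward earlier stages; registry data shows 52.08%
of cancers metastatic/late-stage among women not tested before diagnosis
versus 41.33% among women tested before diagnosis. Under the default
(`"registry"`) an incident breast cancer enters the metastatic state
directly with the group's late-stage probability, and the non-metastatic
state otherwise. This is the only channel by which testing (and
surveillance) improves health outcomes for non-operated carriers and for
negatives; with `"none"` incident cancers all start non-metastatic, the
surveillance subcohort has zero health benefit, and the incremental QALYs
collapse by an order of magnitude. The split applies to first primaries
only; applying it to contralateral recurrences as well makes a high
residual-risk-after-surgery scenario flip to dominance, which contradicts
the reference direction, so it is not done.

**Well-state utility scope (`options.utility_*`).** The utility model is an
age-declining baseline (0.920 at 30, minus 0.00029/year) times a
state-specific multiplier. The high-risk multiplier 0.92 is assigned by
true carrier status: carriers (tested positive or untested) carry it,
non-carriers (tested negative or untested) have the general-population
multiplier 1.0. Assigning by *awareness* instead (all untested women
anxious at 0.92, negatives relieved to 1.0) would credit the testing arm
with an enormous ~1 QALY of pure relief for the 82% testing negative and
drive the ICER below R$ 2,000/QALY, inconsistent with any reported result
of this comparison; assignment by status makes the negative-vs-untested
non-carrier comparison cancel exactly, as the reference deltas require.

Other conventions: no half-cycle correction (membership valued at cycle
start); prophylactic surgery happens at cycle 0 (surgery cost and
first-year utility multiplier then, printed linear recovery increments in
years 2–5, the high-risk well utility from year 6); oophorectomy has no
printed recovery increment, so its multiplier (0.95) returns linearly to
the high-risk level over the same years; women keeping breast tissue after
oophorectomy stay on intensive breast screening while mastectomy/both
groups return to standard care; women tested before diagnosis use the
(cheaper, earlier-stage) relatives' treatment-cost schedule, untested women
and negatives the index schedule.

## Parameters

All inputs live in `inst/extdata/basecase.yaml`: annual transition
probabilities (age-banded where derived per 5-year band), utility
multipliers with their recovery increments, 2021 SUS reimbursement costs in
R$ per health-state year, and the economics block (5% discount rate,
70-year horizon, start age 30, 1-year cycles). Uncertain quantities carry
either a standard deviation or a 95% interval (converted as
`sd = (hi - lo)/3.92`); costs use a 40% sd assumption. The per-woman test
cost is derived as `(1800 + n x 235)/n` for `n` relatives tested per index
case (R$ 1,135 at the default `n = 2`). Any value is addressable by dotted
path (`set_parameter(params, "economics.discount_rate", 0)`), which is how
the deterministic scenarios, the command-line overrides and the acceptance
script operate; `validate_parameters()` returns machine-readable findings
rather than raising.

One printed oddity is kept as printed: the carrier ovarian-cancer risk
0.013 has sd 0.052, which is feasible for a beta fit (feasibility requires
`sd^2 < m(1-m)` = 0.0128) but extremely skewed; together with the
oophorectomy OC risk 0.01 (95% interval 0.0004–0.32) these two dominate the
spread of the PSA cloud. Genuinely infeasible beta inputs are shrunk to
99.9% of the feasible sd bound with a warning.

## Sensitivity analyses

`run_dsa()` clones the base case per scenario bound, re-runs both arms and
reports tornado-sorted ICER pairs; the shipped eight scenarios cover the
discount rate (0/0.10), relatives per index (4/1), residual BC risk after
both surgeries (0/0.08), OC risk after oophorectomy (0.004/0.03), the index
BC treatment schedule (±40%) and the three uptake intervals.

`run_psa()` samples every registered parameter independently (no
correlation structure is imposed), evaluates both arms per draw with shared
draws, and summarises the (dCost, dQALY) cloud as a CEAC and an INMB line
over a WTP grid of 0–150,000 by 500 (covering the R$ 25,000/QALY threshold
discussed for Brazil). Sampled cumulative schedules are made monotone by a
running maximum before conversion. `ceac_threshold()` scans the stored grid
for the first WTP reaching a target probability.

## The synthetic registry

`simulate_cohort()` emulates the individual-level data behind the
probability inputs: index cases and relatives, carriers and non-carriers
(default stratum sizes 275/1,269/356/407), carrier relatives drawing a
prophylaxis choice from the uptake multinomial, and per-subject competing
piecewise-exponential times to BC, OC and death from the band-specific
annual rates, with uniform entry over a 9-year window (administrative
censoring) plus a 2%/year loss-to-follow-up — a value chosen once as
typical for hospital-registry attrition. Entry ages are uniform over 30–60
so every age band is populated. `km_estimate()` (product-limit via the
survival package) treats competing events as censoring — mirroring the
derivation convention; a competing-risks estimator would give strictly
lower cumulative incidence, and this bias is inherited deliberately.
`annual_probability()` converts survival ratios to banded annual
probabilities with pooled Greenwood intervals.

`recover_parameters()` closes the loop: simulate at known truth, estimate,
and report coverage of the 95% intervals across ~25 derivable parameters.
What passing recovery shows is that the estimation pipeline is consistent
with the generator's assumptions (independent censoring, piecewise-constant
hazards, well-specified strata); it cannot show that real registry data
meet those assumptions — informative censoring, age-cohort effects and
competing-risk dependence are exactly what the naive generator does not
emulate.

## Numerical choices and problem sizes

Tolerances: row sums of every transition matrix to 1e-12; trace
conservation to 1e-10; engine-path agreement to 1e-9; the
cumulative/conditional round trip to 1e-12; a two/three-state miniature
against the closed-form geometric-series discounted life years to 1e-9.
Utilities are clamped to [0, 1] with a clamp counter that must stay zero in
the base case. Ties in the synthetic generator are broken by subject order;
event times are reported at 2 decimals.

The test suite runs the full 70-cycle model for all subcohorts, a
10,000-draw PSA twice (seed stability), recovery at 5,000 subjects per
stratum, and 200-replicate coverage simulations at n = 2,000 — sizes chosen
so the whole suite completes in about a minute on one core while keeping
Monte Carlo noise well below the asserted margins.

## Known limitations

* The two structural options that the reference results force
  (per-cycle schedule reading, stage-at-diagnosis split) are calibration
  choices, not observed mechanics; both are single switches away from the
  textbook alternative.
* No half-cycle correction; results slightly undervalue mid-cycle deaths.
* The no-testing comparator inherits the testing cohort's uptake-weighted
  carrier mix but no cascade testing of relatives is modelled; relatives
  enter only through the unit test cost.
* Costs are 2021 SUS reimbursement values in R$; no currency conversion or
  inflation adjustment is provided.
* PSA parameters are sampled independently; correlations (e.g. between
  yearly schedule points) are ignored beyond monotonicity repair.
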