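# Synthetic individual-level time-to-event registry with the statistical
# structure assumed by the parameter-derivation stage, and Kaplan-Meier
# re-derivation of annual transition probabilities from it.

#' Specification for a synthetic testing registry
#'
#' Emulates a hospital registry of women tested for BRCA1/2 germline variants
#' over a fixed window: index cases and relatives, carriers and non-carriers,
#' carrier relatives choosing a prophylactic option, and per-subject
#' time-to-event records for breast cancer, ovarian cancer and death with
#' administrative plus random censoring.
#'
#' @param n_index_carriers,n_index_noncarriers,n_relative_carriers,n_relative_noncarriers
#'   Stratum sizes; defaults follow the registry composition the model's
#'   probabilities were derived from (275 / 1,269 / 356 / 407).
#' @param params A `parameter_set` supplying the true annual event rates and
#'   uptake probabilities (defaults to the shipped base case).
#' @param censor_rate Annual random loss-to-follow-up hazard rate.
#' @param window Follow-up window length in years (testing period span).
#' @param entry_age_range Integer range from which entry ages are drawn
#'   uniformly.
#' @param seed RNG seed recorded in the output.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_index_carriers = 275, n_index_noncarriers = 1269,
                        n_relative_carriers = 356, n_relative_noncarriers = 407,
                        params = default_parameters(), censor_rate = 0.02,
                        window = 9, entry_age_range = c(30, 60), seed = 1) {
  counts <- c(n_index_carriers, n_index_noncarriers, n_relative_carriers,
              n_relative_noncarriers)
  if (any(counts < 0)) stop("cohort_spec: stratum sizes must be >= 0")
  if (censor_rate < 0) stop("cohort_spec: censor_rate must be >= 0")
  structure(list(n_index_carriers = n_index_carriers,
                 n_index_noncarriers = n_index_noncarriers,
                 n_relative_carriers = n_relative_carriers,
                 n_relative_noncarriers = n_relative_noncarriers,
                 params = params, censor_rate = censor_rate, window = window,
                 entry_age_range = entry_age_range, seed = seed),
            class = "cohort_spec")
}

# Piecewise-exponential event times from per-subject-per-year annual event
# probabilities (n x Y matrix). Year k spans (k-1, k]; hazard within year k is
# -log(1 - p[, k]). Returns Inf when no event occurs within Y years.
draw_event_times <- function(p_mat) {
  n <- nrow(p_mat); Y <- ncol(p_mat)
  lam <- -log(1 - p_mat)
  ch <- cbind(0, t(apply(lam, 1, cumsum)))
  if (n == 1) ch <- matrix(ch, 1)
  target <- -log(runif(n))
  k <- rowSums(target > ch[, -1, drop = FALSE])
  time <- rep(Inf, n)
  hit <- k < Y
  kk <- k[hit]
  lam_hit <- lam[cbind(which(hit), kk + 1L)]
  # finite/Inf = 0, so certain-event years (p = 1) fire at the year boundary
  time[hit] <- kk + (target[hit] - ch[cbind(which(hit), kk + 1L)]) / lam_hit
  time
}

#' Simulate an individual-level synthetic registry
#'
#' Each subject draws competing piecewise-exponential times to breast cancer,
#' ovarian cancer and death from the band-specific annual probabilities of the
#' parameter set (modified by the subject's prophylaxis choice), plus an
#' exponential loss-to-follow-up time and administrative censoring at the end
#' of the window given a uniform entry time. The first event wins; ties are
#' impossible almost surely and resolved by the listed event priority.
#' Prophylactic choices are drawn from the uptake multinomial for carrier
#' relatives. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of event records: `subject_id`, `group`, `carrier`,
#'   `prophylaxis`, `entry_age`, `event` (`BC`/`OC`/`death`/`censored`),
#'   `time_to_event` (years from entry, 2 decimals). The seed is attached as
#'   attribute `seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pr <- spec$params$probabilities
  n <- spec$n_index_carriers + spec$n_index_noncarriers +
    spec$n_relative_carriers + spec$n_relative_noncarriers
  group <- rep(c("index", "index", "relative", "relative"),
               c(spec$n_index_carriers, spec$n_index_noncarriers,
                 spec$n_relative_carriers, spec$n_relative_noncarriers))
  carrier <- rep(c(TRUE, FALSE, TRUE, FALSE),
                 c(spec$n_index_carriers, spec$n_index_noncarriers,
                   spec$n_relative_carriers, spec$n_relative_noncarriers))
  prophylaxis <- rep("none", n)
  rel_car <- which(group == "relative" & carrier)
  if (length(rel_car)) {
    probs <- c(mastectomy = pr$uptake_mastectomy,
               oophorectomy = pr$uptake_oophorectomy,
               both = pr$uptake_both)
    probs <- c(probs, none = 1 - sum(probs))
    prophylaxis[rel_car] <- sample(names(probs), length(rel_car),
                                   replace = TRUE, prob = probs)
  }
  entry_age <- sample(spec$entry_age_range[1]:spec$entry_age_range[2], n,
                      replace = TRUE)
  Y <- as.integer(ceiling(spec$window))
  ages <- outer(entry_age, 0:(Y - 1), "+")      # age during follow-up year k

  p_of <- function(abr_or_scalar) {
    if (inherits(abr_or_scalar, "age_banded_rate")) {
      matrix(rate_lookup(abr_or_scalar, ages), n, Y)
    } else matrix(abr_or_scalar, n, Y)
  }
  p_bc <- p_of(pr$well_to_bc_carrier)
  p_bc[!carrier, ] <- p_of(pr$well_to_bc_noncarrier)[!carrier, ]
  p_bc[prophylaxis == "oophorectomy", ] <-
    p_of(pr$well_to_bc_after_oophorectomy)[prophylaxis == "oophorectomy", ]
  p_bc[prophylaxis == "mastectomy", ] <- pr$well_to_bc_after_mastectomy
  p_bc[prophylaxis == "both", ] <- pr$well_to_bc_after_both
  p_oc <- matrix(ifelse(carrier, pr$well_to_oc_carrier, pr$well_to_oc_noncarrier), n, Y)
  p_oc[prophylaxis == "oophorectomy", ] <- pr$well_to_oc_after_oophorectomy
  p_oc[prophylaxis == "mastectomy", ] <- pr$well_to_oc_after_mastectomy
  p_oc[prophylaxis == "both", ] <- pr$well_to_oc_after_both
  p_die <- p_of(pr$all_cause_mortality)

  t_bc <- draw_event_times(p_bc)
  t_oc <- draw_event_times(p_oc)
  t_die <- draw_event_times(p_die)
  t_lost <- if (spec$censor_rate > 0) rexp(n, spec$censor_rate) else rep(Inf, n)
  t_admin <- spec$window - runif(n, 0, spec$window)

  times <- cbind(BC = t_bc, OC = t_oc, death = t_die,
                 censored = pmin(t_lost, t_admin))
  winner <- max.col(-times, ties.method = "first")
  out <- data.frame(subject_id = seq_len(n), group = group, carrier = carrier,
                    prophylaxis = prophylaxis, entry_age = entry_age,
                    event = colnames(times)[winner],
                    time_to_event = round(times[cbind(seq_len(n), winner)], 2),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- spec$seed
  out
}

#' Simulate follow-up within a single cancer state
#'
#' Generates a cohort entering a health state at time 0 with several competing
#' annual-probability transitions (e.g. the breast-cancer state with
#' contralateral recurrence, metastasis, ovarian cancer and cancer death, or
#' the metastatic state with its year-specific conditional death schedule).
#'
#' @param n Number of subjects.
#' @param transitions Named list; each element a vector of annual
#'   probabilities by year since entry (recycled to the window length).
#' @param window Follow-up window in years.
#' @param censor_rate Annual random-censoring hazard.
#' @param seed RNG seed.
#' @return Data frame `subject_id`, `event`, `time_to_event`.
#' @export
simulate_state_cohort <- function(n, transitions, window = 9,
                                  censor_rate = 0.02, seed = 1) {
  set.seed(seed)
  Y <- as.integer(ceiling(window))
  times <- vapply(transitions, function(p) {
    draw_event_times(matrix(rep_len(p, Y), n, Y, byrow = TRUE))
  }, numeric(n))
  if (n == 1) times <- matrix(times, 1, dimnames = list(NULL, names(transitions)))
  t_lost <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  times <- cbind(times, censored = pmin(t_lost, window))
  winner <- max.col(-times, ties.method = "first")
  data.frame(subject_id = seq_len(n), event = colnames(times)[winner],
             time_to_event = round(times[cbind(seq_len(n), winner)], 2),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate for one event type
#'
#' Product-limit estimate treating every competing event as censoring at its
#' occurrence time (the estimator used to derive the model's transition
#' probabilities; it overstates cumulative incidence relative to a
#' competing-risks estimator, see the methods vignette).
#'
#' @param records Event-record data frame (from [simulate_cohort()],
#'   [simulate_state_cohort()] or [read_cohort()]).
#' @param event_of_interest Event label whose time-to-event curve is wanted.
#' @param stratum Optional named list of column filters, e.g.
#'   `list(carrier = TRUE, prophylaxis = "none")`; an empty stratum is an
#'   error naming the filter.
#' @return A `km_curve`: `time` (starting at 0), `surv`, `n_risk`, `n_event`,
#'   `se` (Greenwood standard error of S), `lo`, `hi` (log-transformed 95%
#'   CI), `max_time`.
#' @export
km_estimate <- function(records, event_of_interest, stratum = NULL) {
  if (!is.null(stratum)) {
    for (nm in names(stratum)) {
      records <- records[records[[nm]] %in% stratum[[nm]], , drop = FALSE]
    }
    if (!nrow(records)) {
      stop("empty stratum: ", paste(names(stratum), unlist(stratum),
                                    sep = "=", collapse = ", "))
    }
  }
  if (!nrow(records)) stop("km_estimate: no records")
  status <- as.integer(records$event == event_of_interest)
  fit <- survival::survfit(survival::Surv(records$time_to_event, status) ~ 1,
                           conf.type = "log")
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(fit$n, fit$n.risk), n_event = c(0, fit$n.event),
                 se = c(0, fit$std.err * fit$surv),
                 lo = c(1, fit$lower), hi = c(1, fit$upper),
                 max_time = max(records$time_to_event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, follow-up to %.2f years\n",
              x$n_risk[2], sum(x$n_event), x$max_time))
  invisible(x)
}

# Right-continuous step lookup of S(t).
km_surv_at <- function(curve, t) {
  curve$surv[findInterval(t, curve$time)]
}

#' Annual transition probability from a Kaplan-Meier curve
#'
#' Converts the survival curve into the annual event probability over a band
#' of follow-up years: `p = 1 - (S(b)/S(a))^(1/(b-a))` for years `a+1..b`
#' (for a single year this is `1 - S(t+1)/S(t)`). The confidence interval
#' pools the Greenwood variance increments accumulated across the band.
#'
#' @param curve A `km_curve`.
#' @param years Contiguous integer follow-up years, e.g. `1`, `1:5`, `3:5`.
#' @param conf If `TRUE`, return `c(estimate, lo, hi)` using the pooled
#'   Greenwood 95% interval.
#' @return Annual probability, or a length-3 vector with `conf = TRUE`.
#' @export
annual_probability <- function(curve, years, conf = FALSE) {
  stopifnot(inherits(curve, "km_curve"))
  years <- sort(as.integer(years))
  if (length(years) > 1 && any(diff(years) != 1)) {
    stop("annual_probability: years must be contiguous")
  }
  a <- years[1] - 1L
  b <- years[length(years)]
  if (b > curve$max_time) stop("annual_probability: band extends beyond follow-up")
  Sa <- km_surv_at(curve, a)
  Sb <- km_surv_at(curve, b)
  if (Sa <= 0) stop("annual_probability: no survivors at band start")
  w <- b - a
  R <- Sb / Sa
  p <- 1 - R^(1 / w)
  if (!conf) return(p)
  inside <- curve$time > a & curve$time <= b & curve$n_event > 0
  v <- sum(curve$n_event[inside] /
             (curve$n_risk[inside] * (curve$n_risk[inside] - curve$n_event[inside])))
  se <- sqrt(v)
  lo <- 1 - pmin(R * exp(1.96 * se), 1)^(1 / w)
  hi <- 1 - (R * exp(-1.96 * se))^(1 / w)
  c(estimate = p, lo = lo, hi = hi)
}

# --- full parameter-recovery pipeline ----------------------------------------

#' Re-derive the registry-based model probabilities from synthetic data
#'
#' Runs the whole derivation pipeline in reverse of the model build: simulate
#' a registry (and per-state follow-up cohorts) from the parameter set's true
#' rates, estimate Kaplan-Meier curves, convert to annual probabilities, and
#' report each estimate with its 95% interval beside the true value. Covers
#' the quantities a testing registry can inform: the three surgery uptakes,
#' the six carrier breast-cancer age bands, ovarian-cancer risk for carriers
#' and after oophorectomy, the four breast-cancer-state transition rates, and
#' the two 5-year cumulative death schedules.
#'
#' @param params A `parameter_set`.
#' @param n_per_stratum Subjects per stratum (simulation size).
#' @param seed RNG seed.
#' @return Data frame: `parameter`, `truth`, `estimate`, `lo`, `hi`,
#'   `covered` (truth inside the 95% interval).
#' @export
recover_parameters <- function(params, n_per_stratum = 5000, seed = 1) {
  pr <- params$probabilities
  rows <- list()
  add <- function(parameter, truth, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, truth = truth, estimate = est[[1]],
      lo = est[[2]], hi = est[[3]],
      covered = truth >= est[[2]] & truth <= est[[3]],
      stringsAsFactors = FALSE)
  }

  # registry: carrier relatives for uptake, carrier index cases for incidence
  spec <- cohort_spec(n_index_carriers = n_per_stratum, n_index_noncarriers = 0,
                      n_relative_carriers = n_per_stratum,
                      n_relative_noncarriers = 0, params = params, seed = seed)
  reg <- simulate_cohort(spec)

  relc <- reg[reg$group == "relative", ]
  for (opt in c("mastectomy", "oophorectomy", "both")) {
    x <- sum(relc$prophylaxis == opt); m <- nrow(relc)
    ph <- x / m
    half <- 1.96 * sqrt(ph * (1 - ph) / m)
    add(paste0("uptake_", opt), pr[[paste0("uptake_", opt)]],
        c(ph, ph - half, ph + half))
  }

  unop <- reg[reg$carrier & reg$prophylaxis == "none", ]
  bands <- pr$well_to_bc_carrier$bands
  for (k in seq_len(nrow(bands))) {
    hi_age <- min(bands$age_hi[k], max(reg$entry_age))
    sel <- unop[unop$entry_age >= bands$age_lo[k] & unop$entry_age <= hi_age - 2, ]
    if (!nrow(sel)) next
    cv <- km_estimate(sel, "BC")
    add(sprintf("well_to_bc_carrier_band%d", k), bands$p[k],
        annual_probability(cv, 1:3, conf = TRUE))
  }
  add("well_to_oc_carrier", pr$well_to_oc_carrier,
      annual_probability(km_estimate(unop, "OC"), 1:5, conf = TRUE))
  ooph <- reg[reg$prophylaxis == "oophorectomy", ]
  if (nrow(ooph) > 30) {
    add("well_to_oc_after_oophorectomy", pr$well_to_oc_after_oophorectomy,
        annual_probability(km_estimate(ooph, "OC"), 1:5, conf = TRUE))
  }

  # breast-cancer state: four competing annual rates
  bc_state <- simulate_state_cohort(
    n_per_stratum,
    list(contralateral_BC = pr$recurrence_bc_carrier,
         metastasis = pr$bc_to_metastatic, OC = pr$bc_to_oc,
         death = pr$bc_mortality),
    seed = seed + 1)
  map <- c(contralateral_BC = "recurrence_bc_carrier",
           metastasis = "bc_to_metastatic", OC = "bc_to_oc",
           death = "bc_mortality")
  for (ev in names(map)) {
    add(map[[ev]], pr[[map[[ev]]]],
        annual_probability(km_estimate(bc_state, ev), 1:5, conf = TRUE))
  }

  # five-year cumulative death schedules via their conditional hazards
  sched_recover <- function(field, label, seed_off) {
    sch <- pr[[field]]
    cond <- cumulative_to_conditional(sch)$cond
    st <- simulate_state_cohort(n_per_stratum, list(death = cond),
                                window = 5, censor_rate = 0.02,
                                seed = seed + seed_off)
    cv <- km_estimate(st, "death")
    for (j in 1:5) {
      Sj <- km_surv_at(cv, j)
      inside <- cv$time > 0 & cv$time <= j & cv$n_event > 0
      se <- sqrt(sum(cv$n_event[inside] /
                       (cv$n_risk[inside] * (cv$n_risk[inside] - cv$n_event[inside]))))
      add(sprintf("%s_cum_y%d", label, j), sch$cum[j],
          c(1 - Sj, 1 - pmin(Sj * exp(1.96 * se), 1), 1 - Sj * exp(-1.96 * se)))
    }
  }
  sched_recover("metastatic_death", "metastatic_death", 2)
  sched_recover("oc_death", "oc_death", 3)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- flat-file round trip ----------------------------------------------------

#' Write / read an event-record table as CSV
#'
#' Columns: `subject_id`, `group`, `carrier`, `prophylaxis`, `entry_age`,
#' `event`, `time_to_event`.
#'
#' @param records Event-record data frame.
#' @param path File path.
#' @return `read_cohort()` returns the data frame; `write_cohort()` its path,
#'   invisibly.
#' @export
write_cohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$carrier <- as.logical(out$carrier)
  out
}
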