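# Monthly-cycle cohort simulation: per-cycle transition probabilities,
# trace propagation, discounted cost/QALY accumulation with half-cycle
# correction, and dosing-calendar drug costs.

n_model_cycles <- function(spec) {
  clm <- spec$discount$cycle_length_months
  as.integer(round(spec$horizon_years * 12 / clm))
}

cycle_length_years <- function(spec) spec$discount$cycle_length_months / 12

# Rescale a monthly probability to the model's cycle length (identity for
# the base-case 1-month cycle).
monthly_to_cycle <- function(p, spec) {
  clm <- spec$discount$cycle_length_months
  if (clm == 1) p else rescale_probability(p, 1 / 12, clm / 12)
}

#' Discount factor
#'
#' Annual-compound convention: \eqn{(1 + r)^{-t}}.
#'
#' @param rate Annual discount rate (proportion).
#' @param t Time in years (vectorised).
#' @return Discount factor(s); 1 at \code{t = 0}.
#' @export
discount_factor <- function(rate, t) {
  if (any(t < 0)) config_error("time must be non-negative")
  (1 + rate)^(-t)
}

# Per-cycle hazard inputs for one strategy, before milestone allocation.
# Returns vectors of length n_cycles (cycle k covers ((k-1)*delta, k*delta]).
cycle_hazards <- function(spec, strat, n_cycles) {
  delta <- cycle_length_years(spec)
  tr <- spec$transitions
  arm <- tr[[strat$arm]]
  ns_death <- rep(monthly_to_cycle(arm$ns_death, spec), n_cycles)
  ns_pav <- rep(monthly_to_cycle(arm$ns_pav, spec), n_cycles)
  # sitting: Weibull conditional probability over each cycle, age = model time
  tgrid <- spec$start_age + (0:n_cycles) * delta
  sw <- weibull_survival(tgrid, tr$weibull$lambda, tr$weibull$p)
  sit_death <- 1 - sw[-1] / sw[-length(sw)]
  # walking: life-table annual qx rescaled to the cycle, completed age at
  # cycle start
  age_start <- spec$start_age + (0:(n_cycles - 1)) * delta
  lt <- tr$lifetable
  idx <- findInterval(floor(age_start), lt$age)
  idx[idx < 1L] <- 1L
  walk_death <- rescale_probability(lt$qx[idx], 1, delta)
  pav_death <- rep(monthly_to_cycle(tr$pav_death, spec), n_cycles)
  if (isTRUE(strat$suppress_trial_mortality) && strat$milestone_window_cycles > 0) {
    # no deaths or ventilation were observed during the trial window
    w <- seq_len(min(strat$milestone_window_cycles, n_cycles))
    ns_death[w] <- 0
    ns_pav[w] <- 0
    sit_death[w] <- 0
    walk_death[w] <- 0
  }
  list(ns_death = ns_death, ns_pav = ns_pav, sit_death = sit_death,
       walk_death = walk_death, pav_death = pav_death)
}

# Core cohort recursion. Milestone achievement is allocated against a
# cumulative target schedule (uniform across the trial window): at each
# cycle the transfer tops the achieved cumulative fraction of the starting
# cohort up to target * min(cycle, W)/W, capped by the occupancy available
# after competing exits. Returns the trace and the per-cycle probabilities
# actually applied (used by transition_matrix()).
cohort_engine <- function(spec, strat, n_cycles = n_model_cycles(spec)) {
  hz <- cycle_hazards(spec, strat, n_cycles)
  W <- strat$milestone_window_cycles
  sit_target <- strat$milestone_sit
  walk_target <- strat$milestone_walk

  x <- matrix(0, n_cycles + 1, 5,
              dimnames = list(NULL, health_states()))
  x[1, "not_sitting"] <- 1
  ns_sit <- numeric(n_cycles)
  sit_walk <- numeric(n_cycles)
  achieved_sit <- 0
  achieved_walk <- 0

  ns <- 1; sit <- 0; walk <- 0; pav <- 0; dead <- 0
  for (k in seq_len(n_cycles)) {
    d <- hz$ns_death[k]; v <- hz$ns_pav[k]
    ds <- hz$sit_death[k]; dw <- hz$walk_death[k]; pd <- hz$pav_death[k]

    s_k <- 0
    if (W > 0 && k <= W && sit_target > 0 && ns > 1e-15) {
      want <- sit_target * min(k, W) / W - achieved_sit
      s_k <- min(max(want, 0) / ns, 1 - d - v)
    }
    w_k <- 0
    if (W > 0 && k <= W && walk_target > 0 && sit > 1e-15) {
      want_w <- walk_target * min(k, W) / W - achieved_walk
      w_k <- min(max(want_w, 0) / sit, 1 - ds)
    }
    if (d + v + s_k > 1 + 1e-12)
      config_error(sprintf(
        "outgoing probabilities exceed 1 for state not_sitting at cycle %d", k),
        "smacea_model_error")
    if (ds + w_k > 1 + 1e-12)
      config_error(sprintf(
        "outgoing probabilities exceed 1 for state sitting at cycle %d", k),
        "smacea_model_error")

    moved_sit <- ns * s_k
    moved_walk <- sit * w_k
    dead2 <- dead + ns * d + sit * ds + walk * dw + pav * pd
    pav2 <- pav * (1 - pd) + ns * v
    walk2 <- walk * (1 - dw) + moved_walk
    sit2 <- sit * (1 - ds - w_k) + moved_sit
    ns2 <- ns * (1 - d - v - s_k)

    achieved_sit <- achieved_sit + moved_sit
    achieved_walk <- achieved_walk + moved_walk
    ns <- ns2; sit <- sit2; walk <- walk2; pav <- pav2; dead <- dead2
    x[k + 1, ] <- c(ns, sit, walk, pav, dead)
    ns_sit[k] <- s_k
    sit_walk[k] <- w_k
  }
  list(occupancy = x, hazards = hz, ns_sit = ns_sit, sit_walk = sit_walk)
}

#' Run the cohort simulation for one strategy
#'
#' Propagates the full cohort (starting in `not_sitting`) through the
#' per-cycle transition matrices over the model horizon.
#'
#' @param spec An \code{sma_spec}.
#' @param strat An \code{sma_strategy}, or the name of one of
#'   \code{spec$strategies}.
#' @return An \code{sma_trace}: matrix of state occupancy with one row per
#'   cycle boundary (row 1 = model start), with attributes \code{times}
#'   (years at each boundary), \code{strategy} and the applied milestone
#'   schedules.
#' @export
run_cohort <- function(spec, strat) {
  if (is.character(strat)) strat <- spec$strategies[[strat]]
  if (is.null(strat)) config_error("unknown strategy")
  eng <- cohort_engine(spec, strat)
  x <- eng$occupancy
  structure(x,
            times = (0:(nrow(x) - 1)) * cycle_length_years(spec),
            strategy = strat$name,
            ns_sit = eng$ns_sit, sit_walk = eng$sit_walk,
            hazards = eng$hazards,
            class = c("sma_trace", "matrix"))
}

#' Transition matrix at a given cycle
#'
#' Assembles the row-stochastic 5x5 matrix actually applied at \code{cycle}
#' for a strategy, including any milestone transfer probabilities in force
#' during the trial window (these depend on the cohort's path, so the
#' recursion is run up to the requested cycle).
#'
#' @param spec An \code{sma_spec}.
#' @param strat An \code{sma_strategy} or strategy name.
#' @param cycle Cycle index (1-based).
#' @return 5x5 matrix with rows summing to 1.
#' @export
transition_matrix <- function(spec, strat, cycle) {
  if (is.character(strat)) strat <- spec$strategies[[strat]]
  n <- n_model_cycles(spec)
  if (cycle < 1 || cycle > n)
    config_error(sprintf("cycle %d outside horizon (1..%d)", cycle, n))
  eng <- cohort_engine(spec, strat, n_cycles = cycle)
  hz <- eng$hazards
  k <- cycle
  d <- hz$ns_death[k]; v <- hz$ns_pav[k]; s_k <- eng$ns_sit[k]
  ds <- hz$sit_death[k]; w_k <- eng$sit_walk[k]
  dw <- hz$walk_death[k]; pd <- hz$pav_death[k]
  st <- health_states()
  m <- matrix(0, 5, 5, dimnames = list(from = st, to = st))
  m["not_sitting", ] <- c(1 - d - v - s_k, s_k, 0, v, d)
  m["sitting", ] <- c(0, 1 - ds - w_k, w_k, 0, ds)
  m["walking", ] <- c(0, 0, 1 - dw, 0, dw)
  m["pav", ] <- c(0, 0, 0, 1 - pd, pd)
  m["dead", ] <- c(0, 0, 0, 0, 1)
  m
}

# Occupancy of the dose-eligible states at an arbitrary time (months),
# linearly interpolated between cycle boundaries.
eligible_occupancy <- function(trace, dose_states, tau_months, spec) {
  clm <- spec$discount$cycle_length_months
  pos <- tau_months / clm          # in cycle units
  n <- nrow(trace) - 1
  lo <- pmin(floor(pos), n)
  frac <- pos - lo
  elig <- rowSums(trace[, dose_states, drop = FALSE])
  lo1 <- pmin(lo + 1, n + 1)
  hi1 <- pmin(lo + 2, n + 1)
  elig[lo1] * (1 - frac) + elig[hi1] * frac
}

#' Discounted drug costs over a dosing calendar
#'
#' Each scheduled dose is charged at the per-dose cost times the proportion
#' of the cohort occupying a dose-eligible state at the dose time, discounted
#' to that time. A one-off strategy charges exactly one undiscounted dose to
#' the full cohort at time zero. Maintenance doses recur to the end of the
#' horizon; explicitly listed dose times beyond the horizon are ignored with
#' a warning.
#'
#' @param trace An \code{sma_trace} from [run_cohort()].
#' @param strat The corresponding \code{sma_strategy}.
#' @param spec The \code{sma_spec}.
#' @return Discounted drug cost (AUD per starting patient).
#' @export
dosing_costs <- function(trace, strat, spec) {
  if (is.character(strat)) strat <- spec$strategies[[strat]]
  per_dose <- dose_cost(strat)
  if (per_dose == 0) return(0)
  if (isTRUE(strat$one_off)) return(per_dose)
  horizon_months <- spec$horizon_years * 12
  times <- strat$loading_months
  if (any(times > horizon_months)) {
    warning("dose times beyond the horizon are ignored")
    times <- times[times <= horizon_months]
  }
  if (!is.na(strat$maintenance_interval_months) &&
      !is.na(strat$maintenance_start_month) &&
      strat$maintenance_start_month <= horizon_months) {
    times <- c(times, seq(strat$maintenance_start_month, horizon_months,
                          by = strat$maintenance_interval_months))
  }
  if (length(times) == 0) return(0)
  elig <- eligible_occupancy(trace, strat$dose_states, times, spec)
  disc <- discount_factor(spec$discount$costs, times / 12)
  sum(per_dose * elig * disc)
}

#' Accumulate discounted costs and QALYs from a trace
#'
#' State membership in each cycle is credited as the average of the start-
#' and end-of-cycle occupancy (trapezoidal half-cycle correction, when
#' enabled in the spec). Health-state costs are applied per cycle, utilities
#' are annual QALY weights (per-cycle contribution = utility x cycle length
#' in years), and both streams are discounted at mid-cycle. Drug costs are
#' added via [dosing_costs()].
#'
#' @param trace An \code{sma_trace}.
#' @param spec The \code{sma_spec}.
#' @param strat The strategy the trace was run under.
#' @return An \code{sma_outcome}: list with \code{cost}, \code{qaly},
#'   \code{life_years} (undiscounted), \code{state_cost}, \code{drug_cost},
#'   and per-cycle audit streams \code{cost_stream}, \code{qaly_stream}.
#' @export
accumulate_outcomes <- function(trace, spec, strat) {
  if (is.character(strat)) strat <- spec$strategies[[strat]]
  n <- n_model_cycles(spec)
  if (nrow(trace) != n + 1)
    config_error("trace length does not match the spec horizon")
  delta <- cycle_length_years(spec)
  membership <- if (isTRUE(spec$half_cycle_correction)) {
    (trace[-(n + 1), , drop = FALSE] + trace[-1, , drop = FALSE]) / 2
  } else {
    trace[-(n + 1), , drop = FALSE]
  }
  # state costs are per month of occupancy; scale to the cycle length
  state_cost <- spec$costs$state[health_states()] *
    spec$discount$cycle_length_months
  util <- spec$utilities$mean[health_states()]
  t_mid <- (seq_len(n) - 0.5) * delta
  disc_c <- discount_factor(spec$discount$costs, t_mid)
  disc_e <- discount_factor(spec$discount$effects, t_mid)
  cost_stream <- as.numeric(membership %*% state_cost) * disc_c
  qaly_stream <- as.numeric(membership %*% util) * delta * disc_e
  alive <- setdiff(health_states(), "dead")
  life_years <- sum(membership[, alive]) * delta
  drug <- dosing_costs(trace, strat, spec)
  structure(list(strategy = strat$name,
                 cost = sum(cost_stream) + drug,
                 qaly = sum(qaly_stream),
                 life_years = life_years,
                 state_cost = sum(cost_stream),
                 drug_cost = drug,
                 cost_stream = cost_stream,
                 qaly_stream = qaly_stream),
            class = "sma_outcome")
}

#' Run one strategy end-to-end
#' @inheritParams run_cohort
#' @return An \code{sma_outcome} (the trace is attached as attribute
#'   \code{trace}).
#' @export
run_strategy <- function(spec, strat) {
  if (is.character(strat)) strat <- spec$strategies[[strat]]
  tr <- run_cohort(spec, strat)
  out <- accumulate_outcomes(tr, spec, strat)
  attr(out, "trace") <- tr
  out
}

#' @export
print.sma_outcome <- function(x, ...) {
  cat(sprintf("<sma_outcome> %s: cost $%s, QALYs %.3f, life-years %.2f\n",
              x$strategy, format(round(x$cost), big.mark = ","),
              x$qaly, x$life_years))
  invisible(x)
}

#' Export a trace with per-cycle audit streams as a data frame
#'
#' @param trace An \code{sma_trace}.
#' @param outcome The matching \code{sma_outcome} (optional; adds cost/QALY
#'   streams).
#' @return Data frame: cycle, time (years), five occupancy columns, and when
#'   available the discounted per-cycle cost and QALY streams.
#' @export
trace_to_df <- function(trace, outcome = NULL) {
  df <- data.frame(cycle = 0:(nrow(trace) - 1),
                   time_years = attr(trace, "times"),
                   unclass(trace)[, , drop = FALSE])
  if (!is.null(outcome)) {
    df$cost_stream <- c(NA, outcome$cost_stream)
    df$qaly_stream <- c(NA, outcome$qaly_stream)
  }
  df
}
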