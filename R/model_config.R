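# Model configuration: domain types, validation, base-case preset, file I/O.

#' Health states of the cohort model
#'
#' The model distinguishes five mutually exclusive health states for a cohort
#' of infants with spinal muscular atrophy (SMA) Type I:
#' \describe{
#'   \item{\code{not_sitting}}{SMA Type I, alive, free of permanent assisted
#'     ventilation (PAV); the entry state.}
#'   \item{\code{sitting}}{sitting independently (a Type II-like milestone).}
#'   \item{\code{walking}}{walking independently (a Type III-like milestone).}
#'   \item{\code{pav}}{dependent on permanent assisted ventilation.}
#'   \item{\code{dead}}{absorbing.}
#' }
#'
#' Permitted transitions: \code{not_sitting} may stay or move to
#' \code{sitting}, \code{walking}, \code{pav} or \code{dead}; \code{sitting}
#' and \code{walking} may stay or die; \code{pav} may stay or die;
#' \code{dead} is absorbing.
#'
#' @return Character vector of the five state names, in model order.
#' @export
health_states <- function() {
  c("not_sitting", "sitting", "walking", "pav", "dead")
}

#' Permitted-transition structure
#'
#' @return A 5x5 logical matrix; \code{TRUE} where a transition is allowed.
#' @export
allowed_transitions <- function() {
  s <- health_states()
  m <- matrix(FALSE, 5, 5, dimnames = list(from = s, to = s))
  m["not_sitting", ] <- TRUE
  m["sitting", c("sitting", "walking", "dead")] <- TRUE
  m["walking", c("walking", "dead")] <- TRUE
  m["pav", c("pav", "dead")] <- TRUE
  m["dead", "dead"] <- TRUE
  m
}

# internal: stop with a classed validation error
config_error <- function(msg, class = "smacea_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    config_error(sprintf("%s must lie in [0, 1] (got %s)", what,
                         paste(format(x), collapse = ", ")))
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    config_error(sprintf("%s must be non-negative (got %s)", what,
                         paste(format(x), collapse = ", ")))
  invisible(x)
}

#' Define a treatment strategy
#'
#' A strategy couples a transition-probability arm with a dosing calendar and
#' per-dose cost. Doses are charged to the proportion of the cohort occupying
#' one of \code{dose_states} at the dose time (the alive, ventilation-free
#' states by default), discounted to the dose time; a one-off strategy
#' charges a single dose to the full cohort at time zero.
#'
#' @param name Strategy name, one of \code{"SOC"}, \code{"nusinersen"},
#'   \code{"AVXS-101"} or a custom label.
#' @param arm Which transition-probability set drives the `not_sitting`
#'   state: \code{"soc"} or \code{"treatment"}.
#' @param acquisition_cost Drug acquisition cost per dose (AUD).
#' @param admin_cost Administration/monitoring cost per dose (AUD).
#' @param loading_months Dose times in months for any loading phase.
#' @param maintenance_start_month,maintenance_interval_months Recurring
#'   maintenance doses start/interval (months); \code{NA} for none.
#'   Maintenance continues while the cohort is alive, up to the horizon.
#' @param one_off If \code{TRUE} the strategy has exactly one dose at time 0
#'   charged undiscounted to the full cohort.
#' @param dose_states States in which scheduled doses are charged.
#' @param milestone_sit,milestone_walk Fractions of the starting cohort that
#'   achieve sitting (total, including later walkers) and walking by the end
#'   of the trial window.
#' @param milestone_window_cycles Number of monthly cycles over which the
#'   milestone fractions are allocated uniformly.
#' @param suppress_trial_mortality If \code{TRUE}, death and PAV exits from
#'   `not_sitting` are set to zero during the milestone window (no deaths or
#'   ventilation were observed during the AVXS-101 trial).
#' @return An object of class \code{sma_strategy}.
#' @export
strategy <- function(name,
                     arm = c("soc", "treatment"),
                     acquisition_cost = 0,
                     admin_cost = 0,
                     loading_months = numeric(0),
                     maintenance_start_month = NA_real_,
                     maintenance_interval_months = NA_real_,
                     one_off = FALSE,
                     dose_states = c("not_sitting", "sitting", "walking"),
                     milestone_sit = 0,
                     milestone_walk = 0,
                     milestone_window_cycles = 0,
                     suppress_trial_mortality = FALSE) {
  arm <- match.arg(arm)
  check_nonneg(c(acquisition_cost, admin_cost), sprintf("%s dose costs", name))
  check_prob(c(milestone_sit, milestone_walk), sprintf("%s milestone fractions", name))
  if (milestone_walk > milestone_sit && milestone_sit > 0)
    config_error(sprintf("%s: walkers pass through sitting; milestone_walk cannot exceed milestone_sit", name))
  if (!all(dose_states %in% health_states()))
    config_error(sprintf("%s: unknown dose state", name))
  if (one_off && (length(loading_months) != 1L || loading_months != 0))
    config_error(sprintf("%s: a one-off strategy has exactly one dose at time 0", name))
  structure(
    list(name = name, arm = arm,
         acquisition_cost = acquisition_cost, admin_cost = admin_cost,
         loading_months = as.numeric(loading_months),
         maintenance_start_month = maintenance_start_month,
         maintenance_interval_months = maintenance_interval_months,
         one_off = one_off,
         dose_states = dose_states,
         milestone_sit = milestone_sit,
         milestone_walk = milestone_walk,
         milestone_window_cycles = as.integer(milestone_window_cycles),
         suppress_trial_mortality = suppress_trial_mortality),
    class = "sma_strategy")
}

#' Total per-dose cost of a strategy
#' @param strat An \code{sma_strategy}.
#' @return Acquisition plus administration cost (AUD, unrounded).
#' @export
dose_cost <- function(strat) strat$acquisition_cost + strat$admin_cost

#' Sum itemised administration/monitoring costs
#'
#' @param components Numeric vector of itemised per-dose costs (AUD).
#' @return Their exact sum; no rounding is applied.
#' @export
total_admin_cost <- function(components) {
  if (length(components) == 0) return(0)
  check_nonneg(components, "administration cost components")
  sum(components)
}

#' Total treatment cost per dose
#'
#' @param acquisition Drug acquisition cost (AUD).
#' @param admin Administration and monitoring cost (AUD).
#' @return Unrounded sum. Use \code{round()} only at the display layer.
#' @export
total_dose_cost <- function(acquisition, admin) {
  check_nonneg(c(acquisition, admin), "dose cost components")
  acquisition + admin
}

#' Construct a validated model specification
#'
#' Low-level constructor; most users want [base_case_spec()] or
#' [load_model_spec()]. All component invariants are checked.
#'
#' @param horizon_years Model horizon in years.
#' @param start_age Cohort age at entry (years).
#' @param discount List with \code{costs}, \code{effects} (annual rates) and
#'   \code{cycle_length_months}.
#' @param costs List with per-cycle \code{state} costs (named by state),
#'   optional \code{state_interval} (2-row min/max), \code{drug} acquisition
#'   costs, optional \code{drug_interval}, and \code{admin_items} itemised
#'   administration costs per strategy.
#' @param utilities List with \code{mean} and \code{sd} per state (annual
#'   QALY weights).
#' @param transitions List with per-arm monthly probabilities (\code{soc},
#'   \code{treatment}: each \code{ns_death}, \code{ns_pav}),
#'   \code{pav_death}, a \code{weibull} list (\code{lambda}, \code{p}, time
#'   in years) for sitting-state mortality, and a \code{lifetable}
#'   data.frame (\code{age}, \code{qx}) for walking-state mortality.
#' @param strategies List of [strategy()] objects.
#' @param half_cycle_correction Apply trapezoidal half-cycle correction.
#' @return An object of class \code{sma_spec}.
#' @export
model_spec <- function(horizon_years, start_age, discount, costs, utilities,
                       transitions, strategies, half_cycle_correction = TRUE) {
  spec <- structure(
    list(horizon_years = horizon_years, start_age = start_age,
         discount = discount, costs = costs, utilities = utilities,
         transitions = transitions, strategies = strategies,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "sma_spec")
  validate_model_spec(spec)
}

#' Validate a model specification
#' @param spec An \code{sma_spec}.
#' @return The spec, invisibly usable, after checking every invariant.
#' @export
validate_model_spec <- function(spec) {
  s <- health_states()
  req <- function(x, key) {
    if (is.null(x)) config_error(sprintf("missing required key: %s", key),
                                 class = "smacea_schema_error")
    x
  }
  req(spec$horizon_years, "horizon_years")
  req(spec$discount, "discount")
  req(spec$costs, "costs")
  req(spec$utilities, "utilities")
  req(spec$transitions, "transitions")
  req(spec$strategies, "strategies")
  if (spec$horizon_years <= 0) config_error("horizon_years must be positive")
  if (spec$start_age < 0) config_error("start_age must be non-negative")

  d <- spec$discount
  req(d$costs, "discount$costs"); req(d$effects, "discount$effects")
  req(d$cycle_length_months, "discount$cycle_length_months")
  if (d$costs < 0 || d$costs >= 1 || d$effects < 0 || d$effects >= 1)
    config_error("discount rates must lie in [0, 1)")
  if (d$cycle_length_months <= 0) config_error("cycle length must be positive")

  st <- req(spec$costs$state, "costs$state")
  if (!all(s %in% names(st))) config_error("costs$state must name all five states")
  check_nonneg(unlist(st), "state costs")
  if (st[["pav"]] < st[["not_sitting"]])
    config_error("PAV state cost must be at least the not_sitting state cost")
  check_nonneg(unlist(spec$costs$drug), "drug acquisition costs")

  u <- spec$utilities
  if (!all(s %in% names(u$mean))) config_error("utilities$mean must name all five states")
  check_prob(unlist(u$mean), "utilities")
  if (u$mean[["dead"]] != 0) config_error("utility of dead must be 0")
  check_nonneg(unlist(u$sd), "utility SDs")

  tr <- spec$transitions
  for (arm in c("soc", "treatment")) {
    a <- req(tr[[arm]], paste0("transitions$", arm))
    check_prob(a$ns_death, sprintf("%s not_sitting->death probability", arm))
    check_prob(a$ns_pav, sprintf("%s not_sitting->pav probability", arm))
    if (a$ns_death + a$ns_pav > 1)
      config_error(sprintf("%s arm: not_sitting outgoing probabilities exceed 1", arm))
  }
  check_prob(tr$pav_death, "pav->death probability")
  w <- req(tr$weibull, "transitions$weibull")
  if (w$lambda <= 0 || w$p <= 0)
    config_error("Weibull parameters lambda and p must be positive")
  lt <- req(tr$lifetable, "transitions$lifetable")
  validate_lifetable(lt)

  if (length(spec$strategies) < 1) config_error("at least one strategy required")
  known <- c("SOC", "nusinersen", "AVXS-101")
  for (strat in spec$strategies) {
    if (!inherits(strat, "sma_strategy")) config_error("strategies must be sma_strategy objects")
    if (!strat$name %in% known)
      config_error(sprintf("unknown strategy name: %s", strat$name))
  }
  nm <- vapply(spec$strategies, `[[`, "", "name")
  names(spec$strategies) <- nm
  spec
}

#' Validate a life table
#' @param lt Data frame with columns \code{age} and \code{qx}.
#' @keywords internal
validate_lifetable <- function(lt) {
  if (is.null(lt) || nrow(lt) == 0)
    config_error("life table is empty", class = "smacea_schema_error")
  if (!all(c("age", "qx") %in% names(lt)))
    config_error("life table must have columns age and qx")
  if (lt$age[1] != 0 || any(diff(lt$age) <= 0))
    config_error("life-table ages must increase strictly from 0")
  check_prob(lt$qx, "life-table annual mortality qx")
  invisible(lt)
}

# Table of base-case inputs (2020 AUD; monthly transition probabilities).
# Itemised administration costs follow the national fee schedules.
base_case_inputs <- function() {
  list(
    admin_items = list(
      nusinersen = c(intrathecal_injection_cns = 77.65,
                     intrathecal_injection_csf = 164.4,
                     specialist = 51.5,
                     monitor_thrombocytopenia = 16.95,
                     monitor_renal_toxicity = 9.7,
                     anaesthesia_lumbar_puncture = 102,
                     imaging = 34.3,
                     inpatient_per_diem = 1839,
                     inpatient_anaesthesia = 281),
      avxs101 = c(iv_infusion = 67.1,
                  anti_aav9_test = 15.65,
                  laboratory_monitoring = 17.7,
                  prednisolone = 14.53)),
    drug = list(nusinersen = 110000, avxs101 = 3054344),
    drug_interval = list(nusinersen = c(78804, 146349.45),
                         avxs101 = c(2138121, 3970796)),
    state_cost = c(not_sitting = 23569, sitting = 9896, walking = 6644,
                   pav = 27693, dead = 0),
    state_cost_interval = list(not_sitting = c(16498, 30640),
                               sitting = c(6927, 12865),
                               walking = c(4651, 8637),
                               pav = c(19385, 36001)),
    utility_mean = c(not_sitting = 0.104, sitting = 0.115, walking = 0.252,
                     pav = 0.104, dead = 0),
    utility_sd = c(not_sitting = 0.0278, sitting = 0.0227, walking = 0.0332,
                   pav = 0.0278, dead = 0),
    trans = list(
      soc = list(ns_death = 0.0532, ns_pav = 0.0625),
      treatment = list(ns_death = 0.0184, ns_pav = 0.0355),
      pav_death = 0.0146,
      intervals = list(soc_ns_death = c(0.0372, 0.0692),
                       trt_ns_death = c(0.0129, 0.0239),
                       soc_ns_pav = c(0.0437, 0.0812),
                       trt_ns_pav = c(0.0248, 0.0461),
                       pav_death = c(0.0102, 0.0190)),
      weibull = list(lambda = 0.0006, p = 1.9613, time_unit = "years",
                     lambda_interval = c(0.0002, 0.0017),
                     p_interval = c(1.7226, 2.2331)))
  )
}

#' Base-case model specification
#'
#' The packaged preset used throughout: three strategies (standard of care,
#' nusinersen, AVXS-101) for an SMA Type I birth cohort, monthly cycles over
#' a 100-year horizon, 5\% annual discounting of costs and effects, and
#' trapezoidal half-cycle correction. Monthly transition probabilities for
#' the `not_sitting` and `pav` states come from trial survival; mortality of
#' independent sitters follows a Weibull (\eqn{S(t) = \exp(-\lambda t^p)},
#' \eqn{\lambda = 0.0006}, \eqn{p = 1.9613}, t in years) and of independent
#' walkers the general-population life table.
#'
#' Nusinersen is dosed with four loading doses in months 0--2 and
#' maintenance every four months thereafter, charged while patients are
#' alive and ventilation-free; AVXS-101 is a single dose at time zero.
#' Milestone achievement is allocated uniformly across the trial windows:
#' 8\% of the nusinersen cohort reach independent sitting over 13 months;
#' 11/12 of the AVXS-101 cohort reach sitting (2/12 walking) over 24 months,
#' during which no deaths or ventilation occur.
#'
#' @param lifetable Optional life table (data.frame \code{age}, \code{qx});
#'   defaults to the packaged synthetic low-early-mortality table.
#' @return A validated \code{sma_spec}.
#' @export
base_case_spec <- function(lifetable = NULL) {
  bc <- base_case_inputs()
  if (is.null(lifetable)) lifetable <- synthetic_lifetable()
  admin_nus <- total_admin_cost(bc$admin_items$nusinersen)
  admin_avxs <- total_admin_cost(bc$admin_items$avxs101)
  strategies <- list(
    strategy("SOC", arm = "soc"),
    strategy("nusinersen", arm = "treatment",
             acquisition_cost = bc$drug$nusinersen, admin_cost = admin_nus,
             loading_months = c(0, 0.5, 1, 2),
             maintenance_start_month = 6, maintenance_interval_months = 4,
             dose_states = c("not_sitting", "sitting", "walking"),
             milestone_sit = 0.08, milestone_window_cycles = 13),
    strategy("AVXS-101", arm = "treatment",
             acquisition_cost = bc$drug$avxs101, admin_cost = admin_avxs,
             loading_months = 0, one_off = TRUE,
             milestone_sit = 11 / 12, milestone_walk = 2 / 12,
             milestone_window_cycles = 24,
             suppress_trial_mortality = TRUE))
  model_spec(
    horizon_years = 100, start_age = 0,
    discount = list(costs = 0.05, effects = 0.05, cycle_length_months = 1),
    costs = list(state = bc$state_cost,
                 state_interval = bc$state_cost_interval,
                 drug = bc$drug, drug_interval = bc$drug_interval,
                 admin_items = bc$admin_items),
    utilities = list(mean = bc$utility_mean, sd = bc$utility_sd),
    transitions = list(soc = bc$trans$soc, treatment = bc$trans$treatment,
                       pav_death = bc$trans$pav_death,
                       intervals = bc$trans$intervals,
                       weibull = bc$trans$weibull,
                       lifetable = lifetable),
    strategies = strategies)
}

# --- serialization ---------------------------------------------------------

strategy_to_list <- function(st) {
  out <- unclass(st)
  out$loading_months <- as.numeric(out$loading_months)
  out
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$strategies <- lapply(spec$strategies, strategy_to_list)
  lt <- spec$transitions$lifetable
  out$transitions$lifetable <- list(age = as.numeric(lt$age), qx = as.numeric(lt$qx))
  # named vectors must become maps, or YAML drops the names
  out$costs$state <- as.list(spec$costs$state)
  out$costs$admin_items <- lapply(spec$costs$admin_items, as.list)
  out$utilities <- list(mean = as.list(spec$utilities$mean),
                        sd = as.list(spec$utilities$sd))
  out
}

list_to_spec <- function(x) {
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  strategies <- lapply(x$strategies, function(st) {
    strategy(name = st$name, arm = st$arm,
             acquisition_cost = as.numeric(st$acquisition_cost),
             admin_cost = as.numeric(st$admin_cost),
             loading_months = as.numeric(unlist(st$loading_months)),
             maintenance_start_month = num_or_na(st$maintenance_start_month),
             maintenance_interval_months = num_or_na(st$maintenance_interval_months),
             one_off = isTRUE(st$one_off),
             dose_states = as.character(unlist(st$dose_states)),
             milestone_sit = as.numeric(st$milestone_sit),
             milestone_walk = as.numeric(st$milestone_walk),
             milestone_window_cycles = as.integer(st$milestone_window_cycles),
             suppress_trial_mortality = isTRUE(st$suppress_trial_mortality))
  })
  tr <- x$transitions
  lt <- data.frame(age = as.numeric(unlist(tr$lifetable$age)),
                   qx = as.numeric(unlist(tr$lifetable$qx)))
  unlist_named <- function(v) {
    out <- unlist(v)
    if (is.null(out)) NULL else out
  }
  costs <- x$costs
  costs$state <- unlist_named(costs$state)
  costs$admin_items <- lapply(costs$admin_items, unlist_named)
  model_spec(
    horizon_years = as.numeric(x$horizon_years),
    start_age = as.numeric(x$start_age),
    discount = lapply(x$discount, as.numeric),
    costs = costs,
    utilities = list(mean = unlist_named(x$utilities$mean),
                     sd = unlist_named(x$utilities$sd)),
    transitions = list(soc = lapply(tr$soc, as.numeric),
                       treatment = lapply(tr$treatment, as.numeric),
                       pav_death = as.numeric(tr$pav_death),
                       intervals = tr$intervals,
                       weibull = tr$weibull,
                       lifetable = lt),
    strategies = strategies,
    half_cycle_correction = isTRUE(x$half_cycle_correction))
}

#' Read a model specification from a YAML config file
#'
#' The file mirrors the structure returned by [base_case_spec()]: blocks for
#' discounting, costs, utilities, transition probabilities, the life table
#' and the strategy definitions. Every invariant is validated on load; a
#' missing key raises a schema error naming it, an out-of-range probability
#' a validation error.
#'
#' @param path Path to a YAML file written by [save_model_spec()] (or by hand).
#' @return A validated \code{sma_spec}.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path))
    config_error(sprintf("config file not found: %s", path),
                 class = "smacea_schema_error")
  list_to_spec(yaml::read_yaml(path))
}

#' Write a model specification to a YAML config file
#' @param spec An \code{sma_spec}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_model_spec <- function(spec, path) {
  txt <- yaml::as.yaml(spec_to_list(spec), precision = 15)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.sma_spec <- function(x, ...) {
  cat("<sma_spec> five-state Markov cohort model\n")
  cat(sprintf("  horizon: %g years, cycle: %g month(s), discount: %g%%/%g%% (costs/effects)\n",
              x$horizon_years, x$discount$cycle_length_months,
              100 * x$discount$costs, 100 * x$discount$effects))
  cat("  strategies:", paste(vapply(x$strategies, `[[`, "", "name"),
                             collapse = ", "), "\n")
  invisible(x)
}
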