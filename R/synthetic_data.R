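# Generators for every external input the pipeline needs: trial-like
# right-censored survival data, "published-figure" KM curves with risk
# tables, and a general-population life table.

#' Define a trial simulation scenario
#'
#' @param arm_sizes Named integer vector of patients per arm.
#' @param hazard Per-arm hazard model: named list, each element either
#'   \code{list(dist = "exponential", rate = r)} (rate per month) or
#'   \code{list(dist = "weibull", lambda = l, p = p)} (time in months).
#'   A rate of 0 yields no events (all records administratively censored).
#' @param followup_months Administrative censoring time.
#' @param milestone_fractions Optional named fractions achieving motor
#'   milestones (carried as metadata).
#' @return A \code{trial_scenario} object.
#' @export
trial_scenario <- function(arm_sizes, hazard, followup_months,
                           milestone_fractions = NULL) {
  if (any(arm_sizes < 1)) config_error("arm sizes must be at least 1")
  if (followup_months <= 0) config_error("follow-up must be positive")
  for (h in hazard) {
    if (h$dist == "exponential" && h$rate < 0)
      config_error("hazard rates must be non-negative")
    if (h$dist == "weibull" && (h$lambda <= 0 || h$p <= 0))
      config_error("Weibull hazard parameters must be positive")
  }
  if (!is.null(milestone_fractions))
    check_prob(unlist(milestone_fractions), "milestone fractions")
  structure(list(arm_sizes = arm_sizes, hazard = hazard,
                 followup_months = followup_months,
                 milestone_fractions = milestone_fractions),
            class = "trial_scenario")
}

#' Scenario presets emulating the pivotal-trial structure
#'
#' \code{endear_like()}: a two-arm trial (80 treated, 41 control) with
#' 13-month follow-up; monthly event hazards default to the constant-hazard
#' equivalents of the base-case monthly exit probabilities from the
#' `not_sitting` state (death or ventilation as a composite event).
#' \code{cl101_like()}: a 12-patient single-arm trial with 24-month
#' follow-up and no events (none were observed over the trial window).
#'
#' @return A \code{trial_scenario}.
#' @export
endear_like <- function() {
  trial_scenario(
    arm_sizes = c(treatment = 80, control = 41),
    hazard = list(treatment = list(dist = "exponential",
                                   rate = -log(1 - (0.0184 + 0.0355))),
                  control = list(dist = "exponential",
                                 rate = -log(1 - (0.0532 + 0.0625)))),
    followup_months = 13,
    milestone_fractions = list(treatment_sitting = 0.08, control_sitting = 0))
}

#' @rdname endear_like
#' @export
cl101_like <- function() {
  trial_scenario(
    arm_sizes = c(treatment = 12),
    hazard = list(treatment = list(dist = "exponential", rate = 0)),
    followup_months = 24,
    milestone_fractions = list(sitting = 11 / 12, walking = 2 / 12))
}

draw_event_times <- function(n, h) {
  if (h$dist == "exponential") {
    if (h$rate == 0) rep(Inf, n) else stats::rexp(n, rate = h$rate)
  } else if (h$dist == "weibull") {
    # S(t) = exp(-lambda t^p): invert a uniform
    u <- stats::runif(n)
    (-log(u) / h$lambda)^(1 / h$p)
  } else {
    config_error(sprintf("unknown hazard model: %s", h$dist))
  }
}

#' Simulate right-censored trial survival data
#'
#' Event times are drawn from the per-arm hazard model; all subjects still
#' event-free at the end of follow-up are administratively censored.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @return Named list of data frames (one per arm) with columns \code{time}
#'   (months) and \code{event} (1 event, 0 censored).
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fu <- scenario$followup_months
  out <- lapply(names(scenario$arm_sizes), function(arm) {
    n <- scenario$arm_sizes[[arm]]
    tt <- draw_event_times(n, scenario$hazard[[arm]])
    data.frame(time = pmin(tt, fu), event = as.integer(tt <= fu))
  })
  names(out) <- names(scenario$arm_sizes)
  out
}

#' Turn IPD into a "published-figure" KM curve plus risk table
#'
#' Emulates the digitisation input for curve reconstruction: the
#' Kaplan-Meier step coordinates (optionally perturbed by additive uniform
#' digitisation noise, truncated to [0, 1]) and the numbers at risk at the
#' requested landmark times.
#'
#' @param ipd Data frame with \code{time}, \code{event}.
#' @param landmark_times Times at which numbers at risk are reported; must
#'   start at 0.
#' @param noise Half-width of the uniform perturbation on survival
#'   coordinates (0 = exact).
#' @param seed Optional seed for the noise.
#' @return List with \code{curve} (data.frame \code{time}, \code{surv},
#'   beginning at (0, 1)) and \code{risk} (data.frame \code{time},
#'   \code{n_risk}).
#' @export
publish_km <- function(ipd, landmark_times, noise = 0, seed = NULL) {
  if (nrow(ipd) == 0) config_error("ipd is empty")
  if (length(landmark_times) == 0 || landmark_times[1] != 0)
    config_error("landmark times must start at 0")
  km <- km_estimator(ipd)
  curve <- km$curve
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    keep <- curve$time > 0
    pert <- stats::runif(sum(keep), -noise, noise)
    curve$surv[keep] <- pmin(pmax(curve$surv[keep] + pert, 0), 1)
  }
  n_risk <- vapply(landmark_times, function(tt) {
    sum(ipd$time >= tt)
  }, 0)
  list(curve = curve,
       risk = data.frame(time = landmark_times, n_risk = n_risk))
}

#' Synthetic general-population life table
#'
#' Annual mortality from a Gompertz-Makeham hazard,
#' \eqn{q_x = 1 - \exp(-(a + b c^x))}. The default preset gives infant and
#' childhood mortality below 0.001/year and under 1\% cumulative mortality
#' to age 20, emulating the negligible early-age mortality of a modern
#' high-income population (it stands in for a national life table; no
#' observed population data enter it).
#'
#' @param a Age-independent hazard component (per year).
#' @param b,c Gompertz senescence parameters (\code{b >= 0}, \code{c > 1}).
#' @param max_age Last tabulated age (years).
#' @return Data frame with columns \code{age} and \code{qx}.
#' @export
synthetic_lifetable <- function(a = 2e-4, b = 2e-5, c = 1.1, max_age = 110) {
  if (a < 0 || b < 0) config_error("a and b must be non-negative")
  if (c <= 1) config_error("c must exceed 1")
  age <- 0:max_age
  haz <- a + b * c^age
  qx <- 1 - exp(-haz)
  if (any(qx >= 1))
    config_error("annual mortality reaches 1 before max_age")
  data.frame(age = age, qx = qx)
}
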