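# One-way (tornado) and probabilistic sensitivity analysis, with the
# distribution machinery used to parameterise gamma/beta draws from the
# means, standard deviations and 95% intervals reported for the inputs.

#' Gamma parameters from a mean and a 95% central interval
#'
#' Finds the shape of a gamma distribution whose mean is constrained to
#' \code{mean} and whose 2.5\%/97.5\% quantiles best match \code{lo}/\code{hi}
#' (least squares on the two quantiles). A degenerate interval
#' (\code{lo == hi == mean}) collapses to a fixed value.
#'
#' @param mean Distribution mean (> 0).
#' @param lo,hi Target 2.5\% and 97.5\% quantiles.
#' @return List: \code{family} ("gamma" or "fixed"), \code{shape},
#'   \code{rate}, \code{mean}.
#' @export
gamma_from_mean_interval <- function(mean, lo, hi) {
  if (lo == hi && lo == mean)
    return(list(family = "fixed", mean = mean))
  if (!(0 < lo && lo < mean && mean < hi))
    config_error("need 0 < lo < mean < hi for a gamma interval fit")
  obj <- function(log_shape) {
    shape <- exp(log_shape)
    rate <- shape / mean
    q <- stats::qgamma(c(0.025, 0.975), shape = shape, rate = rate)
    sum(((q - c(lo, hi)) / c(lo, hi))^2)
  }
  # moment start: SD approx interval width / 3.92, shape = (mean/SD)^2
  sd0 <- (hi - lo) / 3.92
  fit <- stats::optim(log((mean / sd0)^2), obj, method = "Brent",
                      lower = log(1e-4), upper = log(1e8))
  shape <- exp(fit$par)
  list(family = "gamma", shape = shape, rate = shape / mean, mean = mean)
}

#' Beta parameters from a mean and a 95% central interval
#'
#' Mean-constrained fit of the concentration \eqn{\nu} (with
#' \eqn{\alpha = \mu\nu, \beta = (1-\mu)\nu}) matching the 2.5\%/97.5\%
#' quantiles by least squares. Used for probabilities whose published
#' uncertainty is a min/max interval.
#'
#' @inheritParams gamma_from_mean_interval
#' @return List: \code{family} ("beta" or "fixed"), \code{alpha},
#'   \code{beta}, \code{mean}.
#' @export
beta_from_mean_interval <- function(mean, lo, hi) {
  if (lo == hi && lo == mean)
    return(list(family = "fixed", mean = mean))
  if (!(0 < lo && lo < mean && mean < hi && hi < 1))
    config_error("need 0 < lo < mean < hi < 1 for a beta interval fit")
  obj <- function(log_nu) {
    nu <- exp(log_nu)
    q <- stats::qbeta(c(0.025, 0.975), mean * nu, (1 - mean) * nu)
    sum(((q - c(lo, hi)) / c(lo, hi))^2)
  }
  sd0 <- (hi - lo) / 3.92
  nu0 <- mean * (1 - mean) / sd0^2 - 1
  fit <- stats::optim(log(max(nu0, 1)), obj, method = "Brent",
                      lower = log(1e-2), upper = log(1e9))
  nu <- exp(fit$par)
  list(family = "beta", alpha = mean * nu, beta = (1 - mean) * nu, mean = mean)
}

#' Beta parameters from a mean and standard deviation
#'
#' Method of moments: \eqn{\alpha = \mu(\mu(1-\mu)/\sigma^2 - 1)},
#' \eqn{\beta = (1-\mu)(\mu(1-\mu)/\sigma^2 - 1)}.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with \code{sd^2 < mean * (1 - mean)}.
#' @return List: \code{family} ("beta" or "fixed" when \code{sd == 0}),
#'   \code{alpha}, \code{beta}, \code{mean}.
#' @export
beta_from_mean_sd <- function(mean, sd) {
  if (sd == 0) return(list(family = "fixed", mean = mean))
  if (mean <= 0 || mean >= 1) config_error("mean must lie strictly in (0, 1)")
  if (sd^2 >= mean * (1 - mean))
    config_error("sd^2 >= mean(1-mean): beta moments infeasible",
                 "smacea_infeasible_moments_error")
  nu <- mean * (1 - mean) / sd^2 - 1
  list(family = "beta", alpha = mean * nu, beta = (1 - mean) * nu, mean = mean)
}

draw_dist <- function(dist, n = 1) {
  switch(dist$family,
         fixed = rep(dist$mean, n),
         gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
         beta = stats::rbeta(n, dist$alpha, dist$beta),
         config_error(sprintf("unknown distribution family: %s", dist$family)))
}

# ---------------------------------------------------------------------------
# Named model parameters: accessor/mutator pairs over an sma_spec, used by
# both the tornado analysis and the PSA.

set_strategy_field <- function(spec, strat, field, value) {
  spec$strategies[[strat]][[field]] <- value
  spec
}

#' Table of perturbable model parameters
#'
#' Each row names a scalar input with a getter/setter over the spec, used by
#' [owsa()] and [run_psa()]. Utilities of the `not_sitting` and `pav` states
#' are a single shared parameter (they are the same value in the base case,
#' and sampling them independently would understate their correlation).
#'
#' @return Named list of parameter definitions (\code{get}, \code{set},
#'   \code{kind}).
#' @export
model_parameters <- function() {
  util_set <- function(states) {
    force(states)
    function(spec, v) {
      v <- min(v, 1)   # utilities capped at 1 after perturbation
      for (s in states) spec$utilities$mean[[s]] <- v
      spec
    }
  }
  prob_set <- function(arm, field) {
    force(arm); force(field)
    function(spec, v) {
      spec$transitions[[arm]][[field]] <- min(v, 1)
      spec
    }
  }
  state_cost_set <- function(state) {
    force(state)
    function(spec, v) { spec$costs$state[[state]] <- v; spec }
  }
  list(
    cost_drug_nusinersen = list(
      kind = "cost",
      get = function(spec) spec$strategies[["nusinersen"]]$acquisition_cost,
      set = function(spec, v) set_strategy_field(spec, "nusinersen", "acquisition_cost", v)),
    cost_drug_avxs101 = list(
      kind = "cost",
      get = function(spec) spec$strategies[["AVXS-101"]]$acquisition_cost,
      set = function(spec, v) set_strategy_field(spec, "AVXS-101", "acquisition_cost", v)),
    cost_admin_nusinersen = list(
      kind = "cost",
      get = function(spec) spec$strategies[["nusinersen"]]$admin_cost,
      set = function(spec, v) set_strategy_field(spec, "nusinersen", "admin_cost", v)),
    cost_admin_avxs101 = list(
      kind = "cost",
      get = function(spec) spec$strategies[["AVXS-101"]]$admin_cost,
      set = function(spec, v) set_strategy_field(spec, "AVXS-101", "admin_cost", v)),
    cost_state_not_sitting = list(
      kind = "cost",
      get = function(spec) spec$costs$state[["not_sitting"]],
      set = state_cost_set("not_sitting")),
    cost_state_sitting = list(
      kind = "cost",
      get = function(spec) spec$costs$state[["sitting"]],
      set = state_cost_set("sitting")),
    cost_state_walking = list(
      kind = "cost",
      get = function(spec) spec$costs$state[["walking"]],
      set = state_cost_set("walking")),
    cost_state_pav = list(
      kind = "cost",
      get = function(spec) spec$costs$state[["pav"]],
      set = state_cost_set("pav")),
    utility_not_sitting_pav = list(
      kind = "utility",
      get = function(spec) spec$utilities$mean[["not_sitting"]],
      set = util_set(c("not_sitting", "pav"))),
    utility_sitting = list(
      kind = "utility",
      get = function(spec) spec$utilities$mean[["sitting"]],
      set = util_set("sitting")),
    utility_walking = list(
      kind = "utility",
      get = function(spec) spec$utilities$mean[["walking"]],
      set = util_set("walking")),
    p_ns_death_soc = list(
      kind = "probability",
      get = function(spec) spec$transitions$soc$ns_death,
      set = prob_set("soc", "ns_death")),
    p_ns_pav_soc = list(
      kind = "probability",
      get = function(spec) spec$transitions$soc$ns_pav,
      set = prob_set("soc", "ns_pav")),
    p_ns_death_treatment = list(
      kind = "probability",
      get = function(spec) spec$transitions$treatment$ns_death,
      set = prob_set("treatment", "ns_death")),
    p_ns_pav_treatment = list(
      kind = "probability",
      get = function(spec) spec$transitions$treatment$ns_pav,
      set = prob_set("treatment", "ns_pav")),
    p_pav_death = list(
      kind = "probability",
      get = function(spec) spec$transitions$pav_death,
      set = function(spec, v) { spec$transitions$pav_death <- min(v, 1); spec }),
    weibull_lambda = list(
      kind = "probability",
      get = function(spec) spec$transitions$weibull$lambda,
      set = function(spec, v) { spec$transitions$weibull$lambda <- v; spec }),
    weibull_p = list(
      kind = "shape",
      get = function(spec) spec$transitions$weibull$p,
      set = function(spec, v) { spec$transitions$weibull$p <- v; spec })
  )
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the pairwise comparison with each parameter set to
#' \code{mean * (1 - span)} and \code{mean * (1 + span)} in turn (all other
#' inputs at base case) and records the ICER at both ends. Perturbed
#' utilities are capped at 1 and probabilities at 1, with the applied value
#' recorded in the output.
#'
#' @param spec An \code{sma_spec}.
#' @param parameters Character vector of parameter names from
#'   [model_parameters()]; default all.
#' @param span Proportional variation (default 0.30).
#' @param comparison Character pair \code{c(a, b)}: ICER of a versus b.
#' @return Data frame sorted by descending ICER range (tornado order):
#'   parameter, base/low/high input values, ICER at each end, range.
#' @export
owsa <- function(spec, parameters = names(model_parameters()), span = 0.30,
                 comparison = c("AVXS-101", "SOC")) {
  defs <- model_parameters()
  unknown <- setdiff(parameters, names(defs))
  if (length(unknown))
    config_error(paste("unknown parameters:", paste(unknown, collapse = ", ")))
  run_icer <- function(sp) {
    a <- run_strategy(sp, comparison[1])
    b <- run_strategy(sp, comparison[2])
    icer(a, b)$icer
  }
  base_icer <- run_icer(spec)
  rows <- lapply(parameters, function(pn) {
    def <- defs[[pn]]
    base <- def$get(spec)
    lo <- base * (1 - span)
    hi <- base * (1 + span)
    sp_lo <- def$set(spec, lo)
    sp_hi <- def$set(spec, hi)
    applied_hi <- def$get(sp_hi)
    if (applied_hi < hi)
      warning(sprintf("%s: high value clipped from %g to %g", pn, hi, applied_hi))
    data.frame(parameter = pn, base_value = base,
               low_value = def$get(sp_lo), high_value = applied_hi,
               icer_low = run_icer(sp_lo), icer_high = run_icer(sp_hi))
  })
  out <- do.call(rbind, rows)
  out$icer_base <- base_icer
  out$range <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  out
}

#' Configure a probabilistic sensitivity analysis
#'
#' Distribution assignments follow the reported input table: gamma for
#' costs (95\% interval = the published min/max where given, otherwise
#' +/-30\% of the mean), beta for utilities (method of moments on the
#' published mean/SD; `not_sitting` and `pav` share one draw) and for
#' transition probabilities (95\% interval = published min/max). The Weibull
#' rate is fitted on the same interval scheme; its shape parameter exceeds 1
#' so a mean-constrained gamma is used for it. Discount rates and the
#' horizon are fixed.
#'
#' @param spec An \code{sma_spec}.
#' @param n Iteration count (>= 1).
#' @param seed Integer seed, recorded in the output.
#' @return \code{sma_psa_config}: list with \code{n}, \code{seed} and the
#'   per-parameter distribution list.
#' @export
psa_config <- function(spec, n = 5000, seed = 1L) {
  if (n < 1) config_error("iteration count must be at least 1")
  iv <- spec$transitions$intervals
  drug_iv <- spec$costs$drug_interval
  state_iv <- spec$costs$state_interval
  pm30 <- function(m) c(0.7 * m, 1.3 * m)
  from_iv <- function(m, iv, fit) {
    if (is.null(iv)) iv <- pm30(m)
    fit(m, iv[1], iv[2])
  }
  u <- spec$utilities
  dists <- list(
    cost_drug_nusinersen = from_iv(spec$strategies[["nusinersen"]]$acquisition_cost,
                                   drug_iv$nusinersen, gamma_from_mean_interval),
    cost_drug_avxs101 = from_iv(spec$strategies[["AVXS-101"]]$acquisition_cost,
                                drug_iv$avxs101, gamma_from_mean_interval),
    cost_admin_nusinersen = from_iv(spec$strategies[["nusinersen"]]$admin_cost,
                                    NULL, gamma_from_mean_interval),
    cost_admin_avxs101 = from_iv(spec$strategies[["AVXS-101"]]$admin_cost,
                                 NULL, gamma_from_mean_interval),
    cost_state_not_sitting = from_iv(spec$costs$state[["not_sitting"]],
                                     state_iv$not_sitting, gamma_from_mean_interval),
    cost_state_sitting = from_iv(spec$costs$state[["sitting"]],
                                 state_iv$sitting, gamma_from_mean_interval),
    cost_state_walking = from_iv(spec$costs$state[["walking"]],
                                 state_iv$walking, gamma_from_mean_interval),
    cost_state_pav = from_iv(spec$costs$state[["pav"]],
                             state_iv$pav, gamma_from_mean_interval),
    utility_not_sitting_pav = beta_from_mean_sd(u$mean[["not_sitting"]],
                                                u$sd[["not_sitting"]]),
    utility_sitting = beta_from_mean_sd(u$mean[["sitting"]], u$sd[["sitting"]]),
    utility_walking = beta_from_mean_sd(u$mean[["walking"]], u$sd[["walking"]]),
    p_ns_death_soc = beta_from_mean_interval(spec$transitions$soc$ns_death,
                                             iv$soc_ns_death[1], iv$soc_ns_death[2]),
    p_ns_pav_soc = beta_from_mean_interval(spec$transitions$soc$ns_pav,
                                           iv$soc_ns_pav[1], iv$soc_ns_pav[2]),
    p_ns_death_treatment = beta_from_mean_interval(spec$transitions$treatment$ns_death,
                                                   iv$trt_ns_death[1], iv$trt_ns_death[2]),
    p_ns_pav_treatment = beta_from_mean_interval(spec$transitions$treatment$ns_pav,
                                                 iv$trt_ns_pav[1], iv$trt_ns_pav[2]),
    p_pav_death = beta_from_mean_interval(spec$transitions$pav_death,
                                          iv$pav_death[1], iv$pav_death[2]),
    weibull_lambda = beta_from_mean_interval(
      spec$transitions$weibull$lambda,
      min(spec$transitions$weibull$lambda_interval),
      max(spec$transitions$weibull$lambda_interval)),
    weibull_p = gamma_from_mean_interval(
      spec$transitions$weibull$p,
      min(spec$transitions$weibull$p_interval),
      max(spec$transitions$weibull$p_interval))
  )
  structure(list(n = as.integer(n), seed = as.integer(seed), dists = dists),
            class = "sma_psa_config")
}

#' Run a probabilistic sensitivity analysis
#'
#' Per iteration, every non-fixed parameter is sampled once and the same
#' draw is applied to all strategies (shared parameters correlate the arms),
#' then each strategy is run and its discounted cost and QALYs recorded.
#' Reproducible: the same seed yields bitwise-identical output.
#'
#' @param spec An \code{sma_spec}.
#' @param cfg An \code{sma_psa_config}; default 5,000 iterations, seed 1.
#' @return \code{sma_psa}: list with \code{samples} (data frame: iteration,
#'   one cost/qaly column pair per strategy), \code{draws} (the sampled
#'   parameter values), \code{seed}, \code{n}.
#' @export
run_psa <- function(spec, cfg = psa_config(spec)) {
  defs <- model_parameters()
  set.seed(cfg$seed)
  pnames <- names(cfg$dists)
  draws <- as.data.frame(lapply(cfg$dists, draw_dist, n = cfg$n))
  strat_names <- names(spec$strategies)
  cost <- matrix(NA_real_, cfg$n, length(strat_names),
                 dimnames = list(NULL, strat_names))
  qaly <- cost
  for (i in seq_len(cfg$n)) {
    sp <- spec
    for (pn in pnames) sp <- defs[[pn]]$set(sp, draws[i, pn])
    for (s in strat_names) {
      out <- run_strategy(sp, s)
      cost[i, s] <- out$cost
      qaly[i, s] <- out$qaly
    }
  }
  samples <- data.frame(iteration = seq_len(cfg$n))
  for (s in strat_names) {
    samples[[paste0("cost_", s)]] <- cost[, s]
    samples[[paste0("qaly_", s)]] <- qaly[, s]
  }
  structure(list(samples = samples, draws = draws,
                 seed = cfg$seed, n = cfg$n,
                 strategies = strat_names),
            class = "sma_psa")
}

#' Cost-effectiveness acceptability curves
#'
#' Pairwise mode: for each willingness-to-pay value, the fraction of PSA
#' iterations in which the first strategy of \code{comparison} has positive
#' incremental net monetary benefit over the second. All-vs-all mode
#' (\code{comparison = NULL}): the fraction of iterations in which each
#' strategy has the maximal NMB; the probabilities sum to 1 at every
#' threshold (ties split evenly).
#'
#' @param psa An \code{sma_psa}.
#' @param wtp_grid Non-empty numeric vector of thresholds (AUD/QALY).
#' @param comparison Character pair, or NULL for all-vs-all.
#' @return Data frame: \code{wtp} plus one probability column (pairwise) or
#'   one per strategy (all-vs-all).
#' @export
ceac <- function(psa, wtp_grid, comparison = c("AVXS-101", "SOC")) {
  if (length(wtp_grid) == 0) config_error("empty willingness-to-pay grid")
  s <- psa$samples
  if (!is.null(comparison)) {
    dc <- s[[paste0("cost_", comparison[1])]] - s[[paste0("cost_", comparison[2])]]
    de <- s[[paste0("qaly_", comparison[1])]] - s[[paste0("qaly_", comparison[2])]]
    prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), 0)
    data.frame(wtp = wtp_grid, probability = prob)
  } else {
    out <- data.frame(wtp = wtp_grid)
    nmbs <- function(w) {
      m <- vapply(psa$strategies,
                  function(st) w * s[[paste0("qaly_", st)]] - s[[paste0("cost_", st)]],
                  numeric(nrow(s)))
      m <- matrix(m, nrow = nrow(s),
                  dimnames = list(NULL, psa$strategies))
      best <- m == apply(m, 1, max)
      colSums(best / rowSums(best)) / nrow(s)
    }
    probs <- t(vapply(wtp_grid, nmbs, numeric(length(psa$strategies))))
    colnames(probs) <- psa$strategies
    cbind(out, probs)
  }
}
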