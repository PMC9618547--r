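# Shared fixtures built in code.

# A minimal single-risk toy spec: one SOC strategy, constant monthly exit
# probabilities, no milestones. Used for closed-form identities.
toy_spec <- function(ns_death = 0, ns_pav = 0, pav_death = 0,
                     horizon_years = 10, discount = 0.05,
                     utility_ns = 0.7, cost_ns = 1000,
                     cycle_length_months = 1,
                     half_cycle_correction = TRUE,
                     strategies = list(strategy("SOC", arm = "soc"))) {
  model_spec(
    horizon_years = horizon_years, start_age = 0,
    discount = list(costs = discount, effects = discount,
                    cycle_length_months = cycle_length_months),
    costs = list(state = c(not_sitting = cost_ns, sitting = 500, walking = 200,
                           pav = cost_ns + 200, dead = 0),
                 drug = list(),
                 admin_items = list()),
    utilities = list(mean = c(not_sitting = utility_ns, sitting = 0.8,
                              walking = 0.9, pav = 0.3, dead = 0),
                     sd = c(not_sitting = 0, sitting = 0, walking = 0,
                            pav = 0, dead = 0)),
    transitions = list(
      soc = list(ns_death = ns_death, ns_pav = ns_pav),
      treatment = list(ns_death = ns_death, ns_pav = ns_pav),
      pav_death = pav_death,
      weibull = list(lambda = 1e-9, p = 1),   # effectively immortal sitters
      lifetable = data.frame(age = 0:110, qx = 0)),
    strategies = strategies,
    half_cycle_correction = half_cycle_correction)
}

# Right-censored draws from S(t) = exp(-lambda t^p) with administrative
# censoring; independent of the package's samplers.
r_weibull_ph <- function(n, lambda, p, cens_time = Inf) {
  tt <- (-log(runif(n)) / lambda)^(1 / p)
  data.frame(time = pmin(tt, cens_time), event = as.integer(tt <= cens_time))
}

expect_rel_error_lt <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
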