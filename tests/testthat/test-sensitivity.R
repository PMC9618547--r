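test_that("beta method-of-moments round-trips the published mean and SD", {
  d <- beta_from_mean_sd(0.252, 0.0332)
  m <- d$alpha / (d$alpha + d$beta)
  v <- d$alpha * d$beta / ((d$alpha + d$beta)^2 * (d$alpha + d$beta + 1))
  expect_equal(m, 0.252, tolerance = 1e-10)
  expect_equal(sqrt(v), 0.0332, tolerance = 1e-10)
  # vanishing SD collapses to the mean
  expect_equal(beta_from_mean_sd(0.3, 0)$family, "fixed")
  d2 <- beta_from_mean_sd(0.3, 1e-4)
  set.seed(1)
  expect_lt(sd(rbeta(1e4, d2$alpha, d2$beta)), 2e-4)
  expect_error(beta_from_mean_sd(0.5, 0.5), "infeasible")
})

test_that("gamma interval fits hit the target quantiles and mean", {
  m <- 110000
  d <- gamma_from_mean_interval(m, 0.7 * m, 1.3 * m)
  q <- qgamma(c(0.025, 0.975), shape = d$shape, rate = d$rate)
  # a mean-constrained gamma cannot match a symmetric interval exactly; the
  # balanced least-squares fit lands within a few percent on each side
  expect_lt(abs(q[1] - 0.7 * m) / (0.7 * m), 0.03)
  expect_lt(abs(q[2] - 1.3 * m) / (1.3 * m), 0.03)
  expect_equal(d$shape / d$rate, m)                 # mean-constrained
  set.seed(2)
  x <- rgamma(1e5, shape = d$shape, rate = d$rate)
  expect_lt(abs(mean(x) - m), 3 * sd(x) / sqrt(1e5))
  expect_equal(gamma_from_mean_interval(5, 5, 5)$family, "fixed")
  expect_error(gamma_from_mean_interval(10, 2, 8), "lo < mean < hi")
})

test_that("beta interval fits cover asymmetric published ranges", {
  d <- beta_from_mean_interval(0.0532, 0.0372, 0.0692)
  q <- qbeta(c(0.025, 0.975), d$alpha, d$beta)
  expect_lt(abs(q[1] - 0.0372) / 0.0372, 0.05)
  expect_lt(abs(q[2] - 0.0692) / 0.0692, 0.05)
  expect_equal(d$alpha / (d$alpha + d$beta), 0.0532, tolerance = 1e-9)
})

test_that("the tornado obeys the affine price relation and zero-influence rule", {
  spec <- base_case_spec()
  tor <- owsa(spec, parameters = c("cost_drug_avxs101", "utility_walking"),
              span = 0.30)
  # closed form: varying the one-off price by +/-30% moves the ICER by
  # exactly 0.3 * price / dQALY in each direction
  soc <- run_strategy(spec, "SOC")
  avxs <- run_strategy(spec, "AVXS-101")
  de <- avxs$qaly - soc$qaly
  price <- spec$strategies[["AVXS-101"]]$acquisition_cost
  row <- tor[tor$parameter == "cost_drug_avxs101", ]
  expect_equal(row$range, 2 * 0.3 * price / de, tolerance = 1e-6)
  expect_equal(row$icer_high - row$icer_base, 0.3 * price / de,
               tolerance = 1e-6)
  # a parameter with no influence on the compared strategies has zero range:
  # the walking state is never reached under nusinersen or SOC
  tor2 <- owsa(spec, parameters = c("utility_walking", "cost_state_walking"),
               comparison = c("nusinersen", "SOC"))
  expect_equal(tor2$range, c(0, 0), tolerance = 1e-9)
})

test_that("the AVXS-101 price dominates its tornado", {
  spec <- base_case_spec()
  tor <- owsa(spec, parameters = c("cost_drug_avxs101", "utility_sitting",
                                   "utility_walking", "cost_state_pav",
                                   "p_pav_death"),
              comparison = c("AVXS-101", "SOC"))
  expect_equal(tor$parameter[1], "cost_drug_avxs101")
  # sitting/walking utilities among the leading drivers
  expect_true(all(c("utility_sitting", "utility_walking") %in%
                    tor$parameter[2:4]))
})

test_that("an all-fixed PSA degenerates to the base case", {
  spec <- base_case_spec()
  cfg <- psa_config(spec, n = 3, seed = 1)
  cfg$dists <- lapply(cfg$dists, function(d) list(family = "fixed",
                                                  mean = d$mean))
  psa <- run_psa(spec, cfg)
  base <- run_cea(spec)$table
  for (nm in base$strategy) {
    expect_equal(unique(psa$samples[[paste0("cost_", nm)]]),
                 base$cost[base$strategy == nm], tolerance = 1e-9)
    expect_equal(unique(psa$samples[[paste0("qaly_", nm)]]),
                 base$qaly[base$strategy == nm], tolerance = 1e-9)
  }
})

test_that("the PSA is bitwise reproducible under a fixed seed", {
  spec <- base_case_spec()
  p1 <- run_psa(spec, psa_config(spec, n = 8, seed = 99))
  p2 <- run_psa(spec, psa_config(spec, n = 8, seed = 99))
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(spec, psa_config(spec, n = 8, seed = 100))
  expect_false(identical(p1$samples, p3$samples))
})

test_that("linear cost parameters pass through the PSA with coefficient one", {
  spec <- base_case_spec()
  # fix everything except the one-off acquisition price: the strategy cost
  # must then equal the sampled price plus a constant, iteration for iteration
  cfg <- psa_config(spec, n = 40, seed = 5)
  keep <- "cost_drug_avxs101"
  cfg$dists[setdiff(names(cfg$dists), keep)] <-
    lapply(cfg$dists[setdiff(names(cfg$dists), keep)],
           function(d) list(family = "fixed", mean = d$mean))
  psa <- run_psa(spec, cfg)
  draws <- psa$draws[[keep]]
  rest <- psa$samples[["cost_AVXS-101"]] - draws
  expect_lt(diff(range(rest)), 1e-6)
  # sampled mean of the price approximates its base value within 3 MC SE
  base_price <- spec$strategies[["AVXS-101"]]$acquisition_cost
  expect_lt(abs(mean(draws) - base_price), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("acceptability curves follow their definitions", {
  spec <- base_case_spec()
  psa <- run_psa(spec, psa_config(spec, n = 60, seed = 7))
  grid <- c(0, 5e5, 2e6, 5e6, 2e7)
  cc <- ceac(psa, grid, comparison = c("AVXS-101", "SOC"))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # at zero willingness to pay the curve is the fraction of cost-saving draws
  dc <- psa$samples[["cost_AVXS-101"]] - psa$samples[["cost_SOC"]]
  expect_equal(cc$probability[cc$wtp == 0], mean(dc < 0))
  # with dQALY > 0 in every draw the pairwise curve is non-decreasing
  de <- psa$samples[["qaly_AVXS-101"]] - psa$samples[["qaly_SOC"]]
  expect_true(all(de > 0))
  expect_true(all(diff(cc$probability) >= 0))
  # far above all sampled ICERs the probability reaches 1
  expect_equal(ceac(psa, max(dc / de) * 2)$probability, 1)
  # all-vs-all probabilities sum to one at every threshold
  all_cc <- ceac(psa, grid, comparison = NULL)
  expect_equal(rowSums(all_cc[, psa$strategies]), rep(1, length(grid)),
               tolerance = 1e-12)
  expect_error(ceac(psa, numeric(0)), "empty")
})

test_that("degenerate PSA gives certainty in the acceptability curve", {
  spec <- base_case_spec()
  cfg <- psa_config(spec, n = 2, seed = 1)
  cfg$dists <- lapply(cfg$dists, function(d) list(family = "fixed",
                                                  mean = d$mean))
  psa <- run_psa(spec, cfg)
  det <- icer(run_strategy(spec, "AVXS-101"), run_strategy(spec, "SOC"))$icer
  expect_equal(ceac(psa, det * 1.05)$probability, 1)
  expect_equal(ceac(psa, det * 0.95)$probability, 0)
})
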