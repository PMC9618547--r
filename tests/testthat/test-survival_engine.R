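test_that("Weibull survival matches its closed forms", {
  expect_equal(weibull_survival(0, 0.0006, 1.9613), 1)
  # median from the closed form, cross-checked by root finding
  lam <- 0.0006; p <- 1.9613
  med_closed <- (log(2) / lam)^(1 / p)
  med_root <- uniroot(function(t) weibull_survival(t, lam, p) - 0.5,
                      c(1, 200), tol = 1e-10)$root
  expect_equal(med_closed, med_root, tolerance = 1e-8)
  expect_equal(med_closed, 36.438, tolerance = 1e-4)
  # direct evaluation at t = 10
  expect_equal(weibull_survival(10, lam, p),
               exp(-lam * exp(p * log(10))), tolerance = 1e-15)
  expect_true(all(diff(weibull_survival(seq(0, 80, 0.5), lam, p)) < 0))
  expect_error(weibull_survival(-1, lam, p), "non-negative")
  expect_error(weibull_survival(1, -0.1, p), "positive")
})

test_that("cycle probability is memoryless for a constant hazard and composes", {
  s_exp <- function(t) exp(-0.12 * t)
  for (t0 in c(0, 3, 17.5))
    expect_equal(cycle_probability(s_exp, t0, 1), 1 - exp(-0.12), tolerance = 1e-12)
  # vanishing interval
  expect_lt(cycle_probability(s_exp, 2, 1e-9), 1e-9)
  # composition over adjacent intervals equals the one-shot probability
  sw <- function(t) weibull_survival(t, 0.0006, 1.9613)
  q1 <- cycle_probability(sw, 10, 1 / 12)
  q2 <- cycle_probability(sw, 10 + 1 / 12, 1 / 12)
  q12 <- cycle_probability(sw, 10, 2 / 12)
  expect_equal((1 - q1) * (1 - q2), 1 - q12, tolerance = 1e-12)
  # brute-force evaluation of the ratio formula
  expect_equal(cycle_probability(sw, 10, 1 / 12),
               1 - sw(10 + 1 / 12) / sw(10), tolerance = 1e-15)
  expect_error(cycle_probability(function(t) 0 * t, 1, 1), "degenerate")
})

test_that("probability rescaling has the constant-hazard closed form and inverts", {
  expect_equal(rescale_probability(0.012, 1, 1 / 12),
               1 - 0.988^(1 / 12), tolerance = 1e-15)
  expect_equal(rescale_probability(0.3, 2, 2), 0.3)
  p <- c(0, 0.0123, 0.5, 0.97)
  expect_equal(rescale_probability(rescale_probability(p, 1, 1 / 12), 1 / 12, 1),
               p, tolerance = 1e-12)
  expect_equal(rescale_probability(1, 1, 1 / 12), 1)
})

test_that("life-table lookup floors age, rescales to monthly, clamps at the end", {
  flat0 <- data.frame(age = 0:100, qx = 0)
  expect_equal(lifetable_monthly_prob(flat0, c(0, 33.7, 250)), c(0, 0, 0))
  lt <- data.frame(age = 0:50, qx = c(rep(0.001, 30), rep(0.012, 21)))
  expect_equal(lifetable_monthly_prob(lt, 30.9), 1 - 0.988^(1 / 12),
               tolerance = 1e-12)
  # beyond the table: last row applies
  expect_equal(lifetable_monthly_prob(lt, 200), 1 - 0.988^(1 / 12),
               tolerance = 1e-12)
  expect_error(lifetable_monthly_prob(data.frame(age = numeric(0),
                                                 qx = numeric(0)), 10),
               "empty")
})

test_that("maximum-likelihood fits recover generating parameters within 3 SE", {
  set.seed(101)
  n <- 1000
  cases <- list(
    exponential = list(gen = function() {
      tt <- rexp(n, 0.1)
      data.frame(time = pmin(tt, 25), event = as.integer(tt <= 25))
    }, truth = c(rate = 0.1)),
    weibull = list(gen = function() r_weibull_ph(n, 0.02, 1.5, cens_time = 30),
                   truth = c(shape = 1.5, scale = 0.02)),
    gompertz = list(gen = function() {
      tt <- flexsurv::rgompertz(n, shape = 0.08, rate = 0.02)
      data.frame(time = pmin(tt, 40), event = as.integer(tt <= 40))
    }, truth = c(shape = 0.08, rate = 0.02)),
    lognormal = list(gen = function() {
      tt <- rlnorm(n, 2, 0.8)
      data.frame(time = pmin(tt, 30), event = as.integer(tt <= 30))
    }, truth = c(meanlog = 2, sdlog = 0.8)),
    loglogistic = list(gen = function() {
      tt <- flexsurv::rllogis(n, shape = 2.2, scale = 9)
      data.frame(time = pmin(tt, 35), event = as.integer(tt <= 35))
    }, truth = c(shape = 2.2, scale = 9))
  )
  for (fam in names(cases)) {
    ipd <- cases[[fam]]$gen()
    fit <- fit_parametric(ipd, fam)
    expect_true(fit$converged, info = fam)
    se <- setNames(fit$flexsurv$res[, "se"], rownames(fit$flexsurv$res))
    for (par in names(cases[[fam]]$truth)) {
      expect_lt(abs(fit$params[[par]] - cases[[fam]]$truth[[par]]),
                3 * se[[par]])
    }
    # information criteria follow their definitions
    expect_equal(fit$aic, 2 * fit$npars - 2 * fit$loglik)
    expect_equal(fit$bic, fit$npars * log(nrow(ipd)) - 2 * fit$loglik)
  }
})

test_that("a simple-rate fit lands inside its own 95% confidence interval", {
  set.seed(11)
  ipd <- data.frame(time = rexp(500, 0.1), event = 1L)
  fit <- fit_parametric(ipd, "exponential")
  ci <- fit$flexsurv$res["rate", c("L95%", "U95%")]
  expect_gt(0.1, ci[[1]])
  expect_lt(0.1, ci[[2]])
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_parametric(data.frame(time = c(1, 2, 3), event = c(1, 0, 0)),
                              "exponential"),
               "not identifiable")
  expect_error(fit_parametric(data.frame(time = c(0, 1), event = c(1, 1)),
                              "weibull"),
               "positive")
})

test_that("AIC prefers the exponential when the Weibull shape is 1", {
  set.seed(12)
  tt <- rexp(800, 0.08)
  ipd <- data.frame(time = pmin(tt, 30), event = as.integer(tt <= 30))
  fe <- fit_parametric(ipd, "exponential")
  fw <- fit_parametric(ipd, "weibull")
  expect_lt(abs(fe$loglik - fw$loglik), 2)   # near-equal likelihoods
  expect_lt(fe$aic, fw$aic)                  # parsimony wins
})

test_that("model selection minimises AIC with BIC then parsimony tie-breaks", {
  set.seed(13)
  ipd <- r_weibull_ph(400, 0.02, 1.5, cens_time = 30)
  fits <- lapply(names(parametric_families()), function(f) fit_parametric(ipd, f))
  best <- select_best(fits)
  sel <- attr(best, "selection")
  expect_equal(best$aic, min(sel$aic))
  expect_equal(nrow(sel), 5)
  # single fit selects itself
  expect_identical(select_best(fits[2])$family, fits[[2]]$family)
  # synthetic tie on AIC: lower BIC wins
  f1 <- structure(list(family = "a", aic = 100, bic = 110, npars = 2,
                       loglik = -48, converged = TRUE), class = "parametric_fit")
  f2 <- structure(list(family = "b", aic = 100, bic = 105, npars = 2,
                       loglik = -48, converged = TRUE), class = "parametric_fit")
  expect_identical(select_best(list(f1, f2))$family, "b")
  expect_error(select_best(list(structure(list(converged = FALSE),
                                          class = "parametric_fit"))),
               "no converged")
  # repeated exponential-truth simulations mostly select the exponential
  set.seed(14)
  wins <- 0
  for (i in 1:10) {
    tt <- rexp(300, 0.1)
    d <- data.frame(time = pmin(tt, 25), event = as.integer(tt <= 25))
    two <- list(fit_parametric(d, "exponential"), fit_parametric(d, "weibull"))
    wins <- wins + (select_best(two)$family == "exponential")
  }
  expect_gte(wins, 6)
})

test_that("Cox-Snell residuals behave as unit-exponential data iff the model fits", {
  set.seed(7)
  d <- r_weibull_ph(400, 0.02, 1.5, cens_time = 30)
  fw <- fit_parametric(d, "weibull")
  rw <- coxsnell_residuals(fw, d)
  expect_equal(nrow(rw), nrow(d))
  expect_true(all(rw$residual >= 0))
  expect_lt(abs(coxsnell_slope(rw) - 1), 0.1)
  # a time-zero event has residual zero
  expect_equal(-log(fw$survival(1e-12)), 0, tolerance = 1e-6)
  # strongly increasing-hazard data fitted with an exponential deviates
  set.seed(8)
  d3 <- r_weibull_ph(400, 0.0005, 3, cens_time = 25)
  slope_ok <- coxsnell_slope(coxsnell_residuals(fit_parametric(d3, "weibull"), d3))
  slope_bad <- coxsnell_slope(coxsnell_residuals(fit_parametric(d3, "exponential"), d3))
  expect_gt(abs(slope_bad - 1), 0.1)
  expect_lt(abs(slope_ok - 1), abs(slope_bad - 1))
  # Weibull MLE cross-checked against the independent survreg route
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = d,
                          dist = "weibull")
  shape_sr <- 1 / sr$scale
  lambda_sr <- exp(-coef(sr)[[1]] * shape_sr)
  expect_equal(fw$params[["shape"]], shape_sr, tolerance = 1e-4)
  expect_equal(fw$params[["scale"]], lambda_sr, tolerance = 1e-4)
})
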