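# Parametric survival functions, hazard/probability conversions and
# life-table background mortality feeding the per-cycle transition matrix.

#' Weibull survival function
#'
#' Uses the proportional-hazards parameterisation
#' \eqn{S(t) = \exp(-\lambda t^p)}, with time in years throughout this
#' package. With \eqn{\lambda = 0.0006, p = 1.9613} this gives a median
#' survival of roughly 36 years for independent sitters.
#'
#' @param t Time (years), non-negative.
#' @param lambda Rate parameter (> 0).
#' @param p Shape parameter (> 0).
#' @return Survival proportion in [0, 1].
#' @export
weibull_survival <- function(t, lambda, p) {
  if (any(t < 0)) config_error("time must be non-negative", "smacea_domain_error")
  if (lambda <= 0 || p <= 0) config_error("lambda and p must be positive")
  exp(-lambda * t^p)
}

#' Per-cycle transition probability from a survival function
#'
#' The conditional probability of the event within \code{(t0, t0 + delta)}
#' given survival to \code{t0}: \eqn{1 - S(t_0 + \delta) / S(t_0)}. For a
#' constant hazard this is \eqn{1 - e^{-h\delta}} independent of \code{t0}.
#'
#' @param survival_fn Function of one argument returning S(t).
#' @param t0 Interval start (years).
#' @param delta Interval length (years), > 0.
#' @return Probability in [0, 1].
#' @export
cycle_probability <- function(survival_fn, t0, delta) {
  if (delta <= 0) config_error("delta must be positive")
  s0 <- survival_fn(t0)
  if (any(s0 <= 0))
    config_error("survival at interval start is zero: degenerate cohort",
                 "smacea_degenerate_error")
  pmin(pmax(1 - survival_fn(t0 + delta) / s0, 0), 1)
}

#' Rescale a probability to a different interval length
#'
#' Converts a probability over an interval of length \code{d1} to the
#' equivalent constant-hazard probability over \code{d2}:
#' \eqn{1 - (1 - p)^{d_2/d_1}}. A probability of exactly 1 stays 1.
#'
#' @param prob Probability in [0, 1].
#' @param d1 Source interval length.
#' @param d2 Target interval length (same unit as \code{d1}).
#' @return Rescaled probability.
#' @export
rescale_probability <- function(prob, d1, d2) {
  check_prob(prob, "probability to rescale")
  if (d1 <= 0 || d2 <= 0) config_error("interval lengths must be positive")
  1 - (1 - prob)^(d2 / d1)
}

#' Monthly mortality from an annual life table
#'
#' Looks up the annual mortality probability \eqn{q_x} for the completed age
#' (ages beyond the table use its last row) and rescales it to a monthly
#' probability under a constant hazard within the year.
#'
#' @param lt Life table: data.frame with columns \code{age} (years, integer
#'   ascending from 0) and \code{qx} (annual mortality probability).
#' @param age Current age in years (may be fractional; vectorised).
#' @return Monthly death probability.
#' @export
lifetable_monthly_prob <- function(lt, age) {
  validate_lifetable(lt)
  if (any(age < 0)) config_error("age must be non-negative")
  idx <- findInterval(floor(age), lt$age)
  idx[idx < 1L] <- 1L
  rescale_probability(lt$qx[idx], 1, 1 / 12)
}

# flexsurv distribution names for the supported families, with their
# parameter counts
parametric_families <- function() {
  c(exponential = "exp", weibull = "weibullPH", gompertz = "gompertz",
    lognormal = "lnorm", loglogistic = "llogis")
}

family_npars <- c(exponential = 1L, weibull = 2L, gompertz = 2L,
                  lognormal = 2L, loglogistic = 2L)

#' Fit a parametric survival model to individual patient data
#'
#' Maximum-likelihood fit with right-censoring for one of five families:
#' exponential, Weibull (proportional-hazards form, matching
#' [weibull_survival()]), Gompertz, log-normal, log-logistic. Reports the
#' log-likelihood, AIC \eqn{= 2k - 2\ell} and BIC \eqn{= k\ln n - 2\ell}
#' (n = number of records).
#'
#' @param ipd Data frame with columns \code{time} (> 0) and \code{event}
#'   (1 = event, 0 = censored).
#' @param family One of \code{names(parametric_families())}.
#' @return An object of class \code{parametric_fit} with elements
#'   \code{family}, \code{params} (natural scale), \code{loglik},
#'   \code{aic}, \code{bic}, \code{npars}, \code{n}, \code{converged}, and
#'   \code{survival} (a function of time).
#' @export
fit_parametric <- function(ipd, family = names(parametric_families())) {
  family <- match.arg(family)
  if (!all(c("time", "event") %in% names(ipd)))
    config_error("ipd must have columns time and event")
  if (any(ipd$time <= 0)) config_error("event/censoring times must be positive")
  if (sum(ipd$event == 1) < 2)
    config_error("fewer than 2 events: model is not identifiable",
                 "smacea_nonidentifiable_error")
  dist <- parametric_families()[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = dist),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(family = family, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "parametric_fit"))
  }
  params <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  k <- length(params)
  n <- nrow(ipd)
  ll <- fit$loglik
  survfun <- local({
    f <- fit
    function(t) summary(f, t = t, type = "survival", ci = FALSE,
                        tidy = TRUE)$est
  })
  structure(list(family = family, params = params, loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 npars = k, n = n, converged = TRUE,
                 survival = survfun, flexsurv = fit),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<parametric_fit> %s: DID NOT CONVERGE (%s)\n",
                x$family, x$message))
    return(invisible(x))
  }
  cat(sprintf("<parametric_fit> %s: logLik %.3f, AIC %.3f, BIC %.3f\n",
              x$family, x$loglik, x$aic, x$bic))
  print(round(x$params, 6))
  invisible(x)
}

#' Cox-Snell residuals of a parametric fit
#'
#' \eqn{r_i = -\ln S(t_i)} under the fitted model, carrying the original
#' censoring indicators. If the model is correct the residuals behave as
#' right-censored unit-exponential data, so the Kaplan-Meier cumulative
#' hazard of the residuals lies on the 45-degree line.
#'
#' @param fit A converged \code{parametric_fit}.
#' @param ipd The data the model was fitted to.
#' @return Data frame with columns \code{residual} and \code{event}.
#' @export
coxsnell_residuals <- function(fit, ipd) {
  if (!isTRUE(fit$converged)) config_error("fit did not converge")
  s <- fit$survival(ipd$time)
  data.frame(residual = -log(s), event = ipd$event)
}

#' Slope of the Cox-Snell residual cumulative hazard
#'
#' Diagnostic summary: regresses the Nelson-Aalen cumulative hazard of the
#' residuals (treated as censored survival times) on the residuals through
#' the origin. Near 1 for a well-specified model.
#'
#' @param resid Output of [coxsnell_residuals()].
#' @return Scalar slope.
#' @export
coxsnell_slope <- function(resid) {
  km <- survival::survfit(survival::Surv(residual, event) ~ 1, data = resid)
  chaz <- cumsum(km$n.event / km$n.risk)
  keep <- km$n.event > 0
  x <- km$time[keep]; y <- chaz[keep]
  sum(x * y) / sum(x * x)
}

#' Select the best parametric fit by information criteria
#'
#' Minimises AIC; ties broken by BIC, then by fewest parameters.
#' Non-converged fits are excluded.
#'
#' @param fits List of \code{parametric_fit} objects.
#' @return The selected fit, with a \code{selection} attribute: a data frame
#'   listing family, logLik, AIC, BIC and parameter count for every
#'   converged candidate.
#' @export
select_best <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0) config_error("no converged fits to select from")
  tab <- data.frame(
    family = vapply(ok, `[[`, "", "family"),
    loglik = vapply(ok, `[[`, 0, "loglik"),
    aic = vapply(ok, `[[`, 0, "aic"),
    bic = vapply(ok, `[[`, 0, "bic"),
    npars = vapply(ok, function(f) as.numeric(f$npars), 0))
  ord <- order(tab$aic, tab$bic, tab$npars)
  best <- ok[[ord[1]]]
  attr(best, "selection") <- tab[ord, ]
  best
}
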