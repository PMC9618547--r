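# Reconstruction of pseudo individual-patient data from digitised
# Kaplan-Meier coordinates plus numbers at risk, and re-estimation of KM
# curves for round-trip validation.

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator (via \code{survival::survfit}); ties are handled
#' events-before-censorings at equal times, the standard convention.
#'
#' @param ipd Data frame with columns \code{time} (>= 0) and \code{event}.
#' @return List with \code{curve}: data.frame (\code{time}, \code{surv})
#'   starting at (0, 1), and \code{fit}: the underlying \code{survfit}.
#' @export
km_estimator <- function(ipd) {
  if (nrow(ipd) == 0) config_error("ipd is empty")
  if (any(ipd$time < 0)) config_error("negative times are not allowed")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  curve <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
  list(curve = curve, fit = fit)
}

#' Survival probability from a KM curve at arbitrary times
#' @param curve Data frame (\code{time}, \code{surv}), a right-continuous
#'   step function.
#' @param t Times at which to evaluate.
#' @return Survival proportions.
#' @export
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  idx[idx < 1L] <- 1L
  curve$surv[idx]
}

validate_km_inputs <- function(curve, risk) {
  if (is.null(curve) || nrow(curve) < 1) config_error("empty KM curve")
  if (curve$time[1] != 0 || curve$surv[1] != 1)
    config_error("KM curve must begin at (0, 1)")
  if (any(diff(curve$time) < 0)) config_error("KM curve times must be non-decreasing")
  check_prob(curve$surv, "KM curve survival")
  if (any(diff(curve$surv) > 1e-9))
    config_error("KM curve survival increases: inconsistent input")
  if (is.null(risk) || nrow(risk) < 1) config_error("empty risk table")
  if (risk$time[1] != 0) config_error("risk table must start at time 0")
  if (any(risk$n_risk < 0) || any(diff(risk$n_risk) > 0))
    config_error("risk-table counts must be non-increasing and non-negative")
  invisible(TRUE)
}

#' Monotonise digitised survival coordinates
#'
#' Digitised points routinely violate monotonicity by hair-widths; this
#' clips to [0, 1] and applies a cumulative minimum, warning when anything
#' changed.
#'
#' @param curve Data frame (\code{time}, \code{surv}).
#' @return The curve with non-increasing survival.
#' @export
monotonise_curve <- function(curve) {
  fixed <- cummin(pmin(pmax(curve$surv, 0), 1))
  if (any(fixed != curve$surv))
    warning("digitised survival coordinates were not monotone; applied cumulative minimum")
  curve$surv <- fixed
  curve
}

# Walk the digitised clicks of one risk-table interval given a censoring
# count: censoring times are spread uniformly over the interval, event
# counts at each click are recovered from the published survival ratios.
# Returns per-click events, censoring times, the running KM value and the
# number still at risk at the interval end.
walk_interval <- function(clicks, n_start, S_prev, c_i, t_k, S_k,
                          int_start, int_end) {
  c_i <- max(0L, min(as.integer(round(c_i)), n_start))
  ct <- if (c_i > 0)
    int_start + (seq_len(c_i) - 0.5) / c_i * (int_end - int_start)
  else numeric(0)
  n <- n_start
  d <- integer(length(clicks))
  S_run <- S_prev
  # censorings before the first click leave the risk set first
  prev_t <- int_start
  for (j in seq_along(clicks)) {
    k <- clicks[j]
    n <- n - sum(ct > prev_t & ct <= t_k[k])
    n <- max(n, 0L)
    if (n > 0 && S_run > 0) {
      dk <- round(n * (1 - S_k[k] / S_run))
      dk <- max(0L, min(as.integer(dk), n))
      if (dk > 0) S_run <- S_run * (1 - dk / n)
      d[j] <- dk
      n <- n - dk
    }
    prev_t <- t_k[k]
  }
  n <- max(n - sum(ct > prev_t & ct <= int_end), 0L)
  list(d = d, cens_times = ct, n_end = n, S_run = S_run)
}

#' Reconstruct pseudo individual-patient data from a published KM curve
#'
#' Implements the iterative censoring-allocation algorithm of Guyot and
#' colleagues. Within each risk-table interval the number of censorings is
#' adjusted iteratively until the implied number at risk at the start of the
#' next interval matches the published count; censoring times are assumed
#' uniform across the interval; event counts at each digitised step are
#' recovered from the published survival ratios, events placed at the step
#' times. After the last risk-table row no further censoring is assumed
#' between steps, and subjects remaining after the last digitised step are
#' censored at the last observed time. If \code{total_events} is supplied,
#' the latest event/censoring labels are flipped to match it.
#'
#' @param curve Data frame (\code{time}, \code{surv}) of digitised
#'   coordinates beginning at (0, 1). Survival that rises by more than
#'   plausible digitisation noise is rejected; hair-width violations are
#'   monotonised with a warning.
#' @param risk Data frame (\code{time}, \code{n_risk}), first row at time 0.
#' @param total_events Optional published total event count.
#' @return Data frame of pseudo-IPD (\code{time}, \code{event}) with exactly
#'   \code{risk$n_risk[1]} rows.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  if (any(diff(curve$surv) > 0.02))
    config_error("KM curve survival increases by more than digitisation noise")
  curve <- monotonise_curve(curve)
  validate_km_inputs(curve, risk)

  t_k <- curve$time
  S_k <- curve$surv
  n_int <- nrow(risk)
  n <- as.integer(risk$n_risk[1])
  n_total <- n
  S_run <- 1
  event_times <- numeric(0)
  cens_times <- numeric(0)

  for (i in seq_len(n_int)) {
    int_start <- risk$time[i]
    int_end <- if (i < n_int) risk$time[i + 1] else max(t_k, risk$time[i])
    clicks <- which(t_k > int_start - 1e-12 & t_k <= int_end +
                      if (i < n_int) -1e-12 else 1e-12)
    clicks <- clicks[t_k[clicks] > 0]   # the (0, 1) anchor carries no events
    target <- if (i < n_int) as.integer(risk$n_risk[i + 1]) else NA_integer_

    if (i < n_int) {
      c_i <- 0L
      best <- NULL
      for (iter in 1:50) {
        res <- walk_interval(clicks, n, S_run, c_i, t_k, S_k, int_start, int_end)
        gap <- res$n_end - target
        if (is.null(best) || abs(gap) < abs(best$gap)) best <- list(res = res, gap = gap, c = c_i)
        if (gap == 0L || (c_i <= 0L && gap < 0L) || c_i >= n) break
        c_i <- max(0L, min(c_i + gap, n))
        if (c_i == best$c && iter > 1) break
      }
      res <- best$res
    } else {
      res <- walk_interval(clicks, n, S_run, 0L, t_k, S_k, int_start, int_end)
    }
    event_times <- c(event_times, rep(t_k[clicks], res$d))
    cens_times <- c(cens_times, res$cens_times)
    n <- res$n_end
    S_run <- res$S_run
  }

  if (n > 0) cens_times <- c(cens_times, rep(max(t_k), n))

  ipd <- rbind(
    if (length(event_times)) data.frame(time = event_times, event = 1L),
    if (length(cens_times)) data.frame(time = cens_times, event = 0L))
  ipd <- ipd[order(ipd$time, -ipd$event), , drop = FALSE]
  rownames(ipd) <- NULL
  stopifnot(nrow(ipd) == n_total)

  if (!is.null(total_events)) {
    have <- sum(ipd$event)
    if (have > total_events) {
      ev <- which(ipd$event == 1L)
      ipd$event[utils::tail(ev, have - total_events)] <- 0L
    } else if (have < total_events) {
      cs <- which(ipd$event == 0L)
      ipd$event[utils::tail(cs, min(length(cs), total_events - have))] <- 1L
    }
  }
  ipd
}
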