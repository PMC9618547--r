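# Incremental cost-effectiveness analysis: pairwise ICERs, net monetary
# benefit, the efficiency frontier, and the acquisition-price threshold
# analysis for the one-off gene therapy.

#' Incremental cost-effectiveness ratio of strategy a versus b
#'
#' Computed from unrounded totals. When the incremental QALYs are negative
#' while incremental costs are positive the comparison is \code{"dominated"};
#' negative costs with positive QALYs is \code{"dominant"}; zero incremental
#' QALYs yields an undefined ICER (only the cost difference is reported).
#'
#' @param a,b \code{sma_outcome} objects from the same model specification.
#' @return List of class \code{sma_icer}: \code{delta_cost},
#'   \code{delta_qaly}, \code{icer} (NA when undefined or dominated) and
#'   \code{label} (\code{"ICER"}, \code{"dominant"}, \code{"dominated"},
#'   \code{"undefined"}).
#' @export
icer <- function(a, b) {
  dc <- a$cost - b$cost
  de <- a$qaly - b$qaly
  if (de == 0) {
    out <- list(delta_cost = dc, delta_qaly = 0, icer = NA_real_,
                label = "undefined")
  } else if (dc < 0 && de > 0) {
    out <- list(delta_cost = dc, delta_qaly = de, icer = dc / de,
                label = "dominant")
  } else if (dc > 0 && de < 0) {
    out <- list(delta_cost = dc, delta_qaly = de, icer = NA_real_,
                label = "dominated")
  } else {
    out <- list(delta_cost = dc, delta_qaly = de, icer = dc / de,
                label = "ICER")
  }
  out$comparison <- paste(a$strategy, "vs", b$strategy)
  structure(out, class = "sma_icer")
}

#' @export
print.sma_icer <- function(x, ...) {
  cat(sprintf("<sma_icer> %s: dCost $%s, dQALY %.3f, %s%s\n",
              x$comparison, format(round(x$delta_cost), big.mark = ","),
              x$delta_qaly, x$label,
              if (!is.na(x$icer)) sprintf(" $%s/QALY",
                                          format(round(x$icer), big.mark = ","))
              else ""))
  invisible(x)
}

#' Net monetary benefit
#' @param outcome An \code{sma_outcome}.
#' @param wtp Willingness-to-pay threshold (AUD per QALY), >= 0.
#' @return \code{wtp * QALYs - cost}.
#' @export
nmb <- function(outcome, wtp) {
  if (any(wtp < 0)) config_error("willingness-to-pay must be non-negative")
  wtp * outcome$qaly - outcome$cost
}

#' Run all strategies and assemble the incremental comparison table
#'
#' @param spec An \code{sma_spec}.
#' @return An object of class \code{sma_cea}: list with \code{outcomes}
#'   (per strategy), \code{comparisons} (pairwise \code{sma_icer}s, each
#'   later-listed strategy versus each earlier one), and \code{table}
#'   (a data frame with unrounded per-strategy and incremental values).
#' @export
run_cea <- function(spec) {
  outcomes <- lapply(spec$strategies, function(st) run_strategy(spec, st))
  names(outcomes) <- names(spec$strategies)
  nm <- names(outcomes)
  comparisons <- list()
  if (length(nm) > 1) {
    for (i in 2:length(nm)) for (j in 1:(i - 1)) {
      cmp <- icer(outcomes[[nm[i]]], outcomes[[nm[j]]])
      comparisons[[paste(nm[i], "vs", nm[j])]] <- cmp
    }
  }
  tab <- data.frame(
    strategy = nm,
    cost = vapply(outcomes, `[[`, 0, "cost"),
    qaly = vapply(outcomes, `[[`, 0, "qaly"),
    life_years = vapply(outcomes, `[[`, 0, "life_years"),
    row.names = NULL)
  structure(list(outcomes = outcomes, comparisons = comparisons, table = tab),
            class = "sma_cea")
}

#' @export
print.sma_cea <- function(x, ...) {
  cat("<sma_cea> per-strategy discounted outcomes\n")
  tab <- x$table
  tab$cost <- format(round(tab$cost), big.mark = ",")
  tab$qaly <- sprintf("%.3f", tab$qaly)
  tab$life_years <- sprintf("%.2f", tab$life_years)
  print(tab, row.names = FALSE)
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Cost-effectiveness frontier
#'
#' Orders strategies by QALYs, flags strictly dominated options (higher cost,
#' no more QALYs than another strategy) and extendedly dominated ones (a
#' higher sequential ICER than the next more effective option), and reports
#' sequential ICERs along the efficient frontier.
#'
#' @param cea An \code{sma_cea} from [run_cea()].
#' @return Data frame: strategy, cost, qaly, status
#'   (\code{"frontier"}, \code{"dominated"}, \code{"ext_dominated"}) and the
#'   sequential ICER against the previous frontier strategy.
#' @export
frontier <- function(cea) {
  tab <- cea$table[order(cea$table$qaly, cea$table$cost), ]
  tab$status <- "frontier"
  tab$sequential_icer <- NA_real_
  # strict dominance
  for (i in seq_len(nrow(tab))) {
    dominated <- any(tab$cost < tab$cost[i] & tab$qaly >= tab$qaly[i] |
                       tab$cost <= tab$cost[i] & tab$qaly > tab$qaly[i])
    if (dominated && any(tab$cost <= tab$cost[i] & tab$qaly >= tab$qaly[i] &
                           seq_len(nrow(tab)) != i))
      tab$status[i] <- "dominated"
  }
  # extended dominance on the remainder
  repeat {
    idx <- which(tab$status == "frontier")
    if (length(idx) < 3) break
    seq_icer <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
    bad <- which(diff(seq_icer) < 0)
    if (!length(bad)) break
    tab$status[idx[bad[1] + 1]] <- "ext_dominated"
  }
  idx <- which(tab$status == "frontier")
  if (length(idx) > 1)
    tab$sequential_icer[idx[-1]] <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
  rownames(tab) <- NULL
  tab
}

#' Acquisition price of AVXS-101 at which its ICER versus SOC equals a
#' willingness-to-pay threshold
#'
#' The one-off dose is charged undiscounted to the full cohort at time zero,
#' so the ICER is affine in the acquisition price with slope
#' \eqn{1/\Delta QALY}; the threshold price has the closed form
#' \deqn{price^* = wtp \cdot \Delta E - (C_{AVXS}^{non-acq} - C_{SOC}),}
#' where \eqn{C_{AVXS}^{non-acq}} is the AVXS-101 strategy cost with the
#' acquisition component removed (administration cost retained). The closed
#' form is verified by re-running the model at the solved price.
#'
#' @param spec An \code{sma_spec} containing the \code{"AVXS-101"} and
#'   \code{"SOC"} strategies.
#' @param wtp Willingness-to-pay (AUD/QALY).
#' @param verify Re-run the model at the solved price and check
#'   |ICER - wtp|/wtp < 1e-6 (skipped for non-positive solutions).
#' @return List of class \code{sma_threshold}: \code{wtp}, \code{price}
#'   (NA when no non-negative price exists), \code{raw_price} (the closed
#'   form, possibly negative) and \code{cost_effective_at_any_price} flag.
#' @export
threshold_price <- function(spec, wtp, verify = TRUE) {
  if (!all(c("AVXS-101", "SOC") %in% names(spec$strategies)))
    config_error("threshold analysis needs the AVXS-101 and SOC strategies")
  avxs <- run_strategy(spec, "AVXS-101")
  soc <- run_strategy(spec, "SOC")
  de <- avxs$qaly - soc$qaly
  if (de <= 0) config_error("AVXS-101 yields no incremental QALYs over SOC")
  st <- spec$strategies[["AVXS-101"]]
  nonacq <- avxs$cost - st$acquisition_cost   # admin + state costs
  raw <- wtp * de - (nonacq - soc$cost)
  feasible <- raw >= 0
  if (feasible && verify) {
    spec2 <- set_avxs_price(spec, raw)
    a2 <- run_strategy(spec2, "AVXS-101")
    ic <- (a2$cost - soc$cost) / (a2$qaly - soc$qaly)
    if (abs(ic - wtp) / wtp > 1e-6)
      config_error("threshold price verification failed")
  }
  structure(list(wtp = wtp, price = if (feasible) raw else NA_real_,
                 raw_price = raw,
                 not_cost_effective = !feasible,
                 delta_qaly = de),
            class = "sma_threshold")
}

#' Replace the AVXS-101 acquisition price in a spec
#' @param spec An \code{sma_spec}.
#' @param price New acquisition cost per dose (AUD).
#' @return The modified, re-validated spec.
#' @export
set_avxs_price <- function(spec, price) {
  check_nonneg(price, "acquisition price")
  st <- spec$strategies[["AVXS-101"]]
  if (is.null(st)) config_error("no AVXS-101 strategy in spec")
  st$acquisition_cost <- price
  spec$strategies[["AVXS-101"]] <- st
  spec$costs$drug$avxs101 <- price
  validate_model_spec(spec)
}

#' @export
print.sma_threshold <- function(x, ...) {
  if (x$not_cost_effective) {
    cat(sprintf("<sma_threshold> WTP $%s/QALY: not cost-effective at any non-negative price (closed form $%s)\n",
                format(x$wtp, big.mark = ","),
                format(round(x$raw_price), big.mark = ",")))
  } else {
    cat(sprintf("<sma_threshold> WTP $%s/QALY: threshold acquisition price $%s\n",
                format(x$wtp, big.mark = ","),
                format(round(x$price), big.mark = ",")))
  }
  invisible(x)
}
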