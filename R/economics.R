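# Discounted costs, life years, QALYs and incremental cost-effectiveness.
# All accumulation runs over half-cycle-corrected occupancy for cycles
# 1..H; the default discount exponent t - 0.5 matches the mid-cycle
# crediting of the corrected occupancy (end-of-cycle exponent t is
# available via settings$discount_timing = "end_cycle").

discount_factors <- function(n, rate, timing = "half_cycle") {
  if (n == 0) return(numeric(0))
  expo <- if (timing == "half_cycle") seq_len(n) - 0.5 else seq_len(n)
  (1 + rate)^(-expo)
}

#' Discount a per-cycle stream to present value
#'
#' @param values Per-cycle values (cycle 1 first).
#' @param rate Annual discount rate (>= 0).
#' @param timing `"half_cycle"` (exponent t - 0.5, default) or
#'   `"end_cycle"` (exponent t).
#' @return The discounted sum (0 for an empty stream).
#' @export
#' @examples
#' discount_stream(c(100, 100), 0.03) # 100/1.03^0.5 + 100/1.03^1.5
discount_stream <- function(values, rate, timing = c("half_cycle", "end_cycle")) {
  timing <- match.arg(timing)
  stopifnot(rate >= 0)
  sum(values * discount_factors(length(values), rate, timing))
}

trial_weight <- function(params) lc_trial_year_cost_weight(params$settings$lc_trial_weeks)

#' Per-cycle drug-cost stream of one arm (per entering patient)
#'
#' Predialysis occupancy is charged the arm's regimen at the
#' predialysis annual cost; dialysis subgroups at their own regimen's
#' dialysis cost. Arms flagged for the second-line trial pay the
#' blended 8-week LC / 44-week CB cost in their first predialysis
#' cycle; dialysis subgroups flagged `lc_trial_on_entry` pay the LC-CB
#' cost difference for the trial weeks on their arrival fraction.
#'
#' @param trace A `phoscea_trace` from [run_cohort()].
#' @param params A `phoscea_parameters` object.
#' @return Numeric vector of length H (EUR per entering patient, cycle
#'   1 first, undiscounted).
#' @export
arm_drug_cost_stream <- function(trace, params) {
  arm <- trace$arm
  H <- trace$cycles
  w <- trial_weight(params)
  cost_pre <- c(cb = cb_annual_cost(params, "predialysis"),
                lc = drug_annual_cost(params, "lc", "predialysis"))
  cost_dial <- c(cb = cb_annual_cost(params, "dialysis"),
                 lc = drug_annual_cost(params, "lc", "dialysis"))
  corr <- trace$corrected
  pre_cost_per_year <- rep(cost_pre[[arm$drug]], H)
  if (isTRUE(arm$lc_trial_first_cycle) && H >= 1) {
    pre_cost_per_year[1] <- w$lc_fraction * cost_pre[["lc"]] +
      w$cb_fraction * cost_pre[["cb"]]
  }
  out <- corr[, 1] * pre_cost_per_year
  mix <- arm$dialysis_mix
  for (k in seq_len(nrow(mix))) {
    out <- out + corr[, 1 + k] * cost_dial[[mix$drug[k]]]
    if (isTRUE(mix$lc_trial_on_entry[k])) {
      out <- out + trace$inflow[, k] * w$lc_fraction *
        (cost_dial[["lc"]] - cost_dial[["cb"]])
    }
  }
  unname(out)
}

#' Per-cycle QALY stream of one arm (per entering patient)
#'
#' Corrected predialysis occupancy weighted by the predialysis utility
#' plus dialysis occupancy weighted by the dialysis utility, minus the
#' vomiting disutility on LC-treated occupancy (annual episode rate
#' times the per-episode utility decrement; trial arms accrue the
#' trial-weeks fraction of it).
#'
#' @inheritParams arm_drug_cost_stream
#' @return Numeric vector of length H (QALYs per entering patient,
#'   undiscounted).
#' @export
arm_qaly_stream <- function(trace, params) {
  arm <- trace$arm
  ut <- params$utilities
  H <- trace$cycles
  w <- trial_weight(params)
  corr <- trace$corrected
  out <- corr[, 1] * ut$utility_predialysis
  vomit_pre <- ut$vomit_rate_lc_predialysis * ut$vomit_decrement
  vomit_dial <- ut$vomit_rate_lc_dialysis * ut$vomit_decrement
  if (identical(arm$drug, "lc")) out <- out - corr[, 1] * vomit_pre
  if (isTRUE(arm$lc_trial_first_cycle) && H >= 1) {
    out[1] <- out[1] - corr[1, 1] * w$lc_fraction * vomit_pre
  }
  mix <- arm$dialysis_mix
  for (k in seq_len(nrow(mix))) {
    out <- out + corr[, 1 + k] * ut$utility_dialysis
    if (identical(mix$drug[k], "lc")) out <- out - corr[, 1 + k] * vomit_dial
    if (isTRUE(mix$lc_trial_on_entry[k])) {
      out <- out - trace$inflow[, k] * w$lc_fraction * vomit_dial
    }
  }
  unname(out)
}

strategy_streams <- function(run, params) {
  # Cohort-fraction-weighted per-cycle streams for a whole strategy,
  # per entering patient, undiscounted.
  H <- params$settings$horizon_years
  drug <- qaly <- numeric(H)
  for (i in seq_along(run$arms)) {
    f <- run$arms[[i]]$fraction
    drug <- drug + f * arm_drug_cost_stream(run$traces[[i]], params)
    qaly <- qaly + f * arm_qaly_stream(run$traces[[i]], params)
  }
  list(drug = drug,
       qaly = qaly,
       predialysis = unname(run$corrected[, "predialysis"]),
       dialysis = unname(run$corrected[, "dialysis"]),
       alive = unname(run$corrected[, "predialysis"] + run$corrected[, "dialysis"]))
}

#' Dialysis facility-cost streams for the two strategies
#'
#' Under `future_dialysis_cost_mode = "attributable_only"` (base case)
#' the only dialysis cost attributable to binder choice is the dialysis
#' time the comparator avoids by delaying progression: each strategy is
#' charged the annual dialysis cost per cycle on the comparator's
#' excess *predialysis* occupancy (floored at zero) — the dialysis
#' years the comparator converted into dialysis-free years. Extra
#' dialysis occupancy that reflects longer survival is dialysis care in
#' added life years, an unrelated future cost, and is never charged; in
#' the base case the second-line-LC strategy therefore incurs no
#' dialysis cost, and the CB strategy is charged one dialysis year per
#' discounted dialysis-free year gained by LC. Under `"full"` every
#' dialysis occupancy unit is charged in both strategies.
#'
#' @param dial_cb,dial_lc Corrected per-cycle dialysis occupancy of the
#'   continued-CB and second-line-LC strategies (same horizon).
#' @param params A `phoscea_parameters` object.
#' @param pre_cb,pre_lc Corrected per-cycle predialysis occupancy;
#'   required for `attributable_only`.
#' @return List of two undiscounted per-cycle EUR streams (`cb`, `lc`),
#'   per entering patient.
#' @export
dialysis_cost_streams <- function(dial_cb, dial_lc, params,
                                  pre_cb = NULL, pre_lc = NULL) {
  if (length(dial_cb) != length(dial_lc)) {
    stop("strategy traces must share the same horizon", call. = FALSE)
  }
  unit <- params$settings$dialysis_annual_cost
  if (params$settings$future_dialysis_cost_mode == "attributable_only") {
    if (is.null(pre_cb) || is.null(pre_lc)) {
      stop("attributable_only costing needs predialysis-occupancy streams",
           call. = FALSE)
    }
    list(cb = pmax(0, pre_lc - pre_cb) * unit,
         lc = pmax(0, pre_cb - pre_lc) * unit)
  } else {
    list(cb = dial_cb * unit, lc = dial_lc * unit)
  }
}

#' Incremental discounted dialysis-free years
#'
#' Sum over cycles of the discounted excess predialysis occupancy of
#' the LC strategy over the CB strategy, floored at zero per cycle and
#' scaled to the cohort.
#'
#' @param pre_lc,pre_cb Corrected per-cycle predialysis occupancy per
#'   entering patient, LC and CB strategies.
#' @param params A `phoscea_parameters` object.
#' @return Discounted dialysis-free years gained for the cohort.
#' @export
dialysis_free_years <- function(pre_lc, pre_cb, params) {
  st <- params$settings
  discount_stream(pmax(0, pre_lc - pre_cb), st$discount_rate, st$discount_timing) *
    st$cohort_size
}

strategy_result <- function(streams, dialysis_cost_stream, params) {
  st <- params$settings
  dsc <- function(v) discount_stream(v, st$discount_rate, st$discount_timing)
  n <- st$cohort_size
  drug_cost <- dsc(streams$drug) * n
  dialysis_cost <- dsc(dialysis_cost_stream) * n
  structure(list(
    life_years = dsc(streams$alive) * n,
    dialysis_free_life_years = dsc(streams$predialysis) * n,
    qalys = dsc(streams$qaly) * n,
    drug_cost = drug_cost,
    dialysis_cost = dialysis_cost,
    total_cost = drug_cost + dialysis_cost,
    per_patient = list(
      life_years = dsc(streams$alive),
      qalys = dsc(streams$qaly),
      drug_cost = drug_cost / n,
      dialysis_cost = dialysis_cost / n,
      total_cost = (drug_cost + dialysis_cost) / n
    )
  ), class = "phoscea_arm_result")
}

#' Incremental cost-effectiveness comparison
#'
#' Computes deltas (LC minus CB), classifies dominance from the signs
#' of incremental cost and incremental QALYs, reports ICERs per QALY
#' and per life year only in the trade-off quadrants (a dominance label
#' otherwise), and the net monetary benefit
#' `NMB = lambda * delta_QALYs - delta_cost`.
#'
#' @param cb,lc Strategy results from the same parameter set.
#' @param lambda Willingness-to-pay threshold in EUR/QALY.
#' @return A `phoscea_ce_result` list with `delta_cost`, `delta_qalys`,
#'   `delta_ly`, `delta_dialysis_free_years`, `icer_per_qaly`,
#'   `icer_per_ly`, `nmb`, `dominance`.
#' @export
incremental <- function(cb, lc, lambda) {
  dC <- lc$total_cost - cb$total_cost
  dQ <- lc$qalys - cb$qalys
  dL <- lc$life_years - cb$life_years
  dominance <-
    if (dC < 0 && dQ > 0) "dominant"
    else if (dC > 0 && dQ < 0) "dominated"
    else if (dC >= 0 && dQ >= 0) "tradeoff_NE"
    else "tradeoff_SW"
  icer <- function(dE) {
    if (dominance %in% c("dominant", "dominated")) dominance
    else if (abs(dE) < .Machine$double.eps^0.75) {
      if (abs(dC) < .Machine$double.eps^0.75) "no_difference" else "undefined"
    } else dC / dE
  }
  structure(list(
    delta_cost = dC, delta_qalys = dQ, delta_ly = dL,
    icer_per_qaly = icer(dQ), icer_per_ly = icer(dL),
    nmb = lambda * dQ - dC, lambda = lambda, dominance = dominance
  ), class = "phoscea_ce_result")
}

#' Run the full cost-effectiveness pipeline
#'
#' Builds both strategies' decision trees, runs the Markov cohort per
#' arm, accumulates discounted costs and outcomes, and compares the
#' second-line LC strategy against continued CB.
#'
#' @param params A `phoscea_parameters` object (defaults to the bundled
#'   base case).
#' @return A `phoscea_ce` list: `cb` and `lc` strategy results (cohort
#'   and per-patient blocks), `incremental`, `dialysis_free_years`
#'   (cohort), the two strategy runs, and the parameters used.
#' @export
#' @examples
#' ce <- run_ce(default_parameters())
#' ce$incremental$dominance
run_ce <- function(params = default_parameters()) {
  run_cb <- run_strategy(params, "cb")
  run_lc <- run_strategy(params, "lc")
  s_cb <- strategy_streams(run_cb, params)
  s_lc <- strategy_streams(run_lc, params)
  dial <- dialysis_cost_streams(s_cb$dialysis, s_lc$dialysis, params,
                                pre_cb = s_cb$predialysis, pre_lc = s_lc$predialysis)
  res_cb <- strategy_result(s_cb, dial$cb, params)
  res_lc <- strategy_result(s_lc, dial$lc, params)
  inc <- incremental(res_cb, res_lc, params$settings$threshold_lambda)
  inc$delta_dialysis_free_years <-
    dialysis_free_years(s_lc$predialysis, s_cb$predialysis, params)
  structure(list(cb = res_cb, lc = res_lc, incremental = inc,
                 dialysis_free_years = inc$delta_dialysis_free_years,
                 runs = list(cb = run_cb, lc = run_lc), params = params),
            class = "phoscea_ce")
}

#' @export
print.phoscea_ce <- function(x, ...) {
  fmtk <- function(v) formatC(v / 1000, format = "f", digits = 0, big.mark = ",")
  cat("Cost-effectiveness: second-line LC vs continued CB\n")
  cat(sprintf("  QALYs (cohort):   CB %.1f   LC %.1f   delta %.2f\n",
              x$cb$qalys, x$lc$qalys, x$incremental$delta_qalys))
  cat(sprintf("  Total cost (EUR thousand): CB %s   LC %s   delta %s\n",
              fmtk(x$cb$total_cost), fmtk(x$lc$total_cost),
              fmtk(x$incremental$delta_cost)))
  cat(sprintf("  Dialysis-free years gained: %.1f\n", x$dialysis_free_years))
  icer <- x$incremental$icer_per_qaly
  cat(sprintf("  ICER per QALY: %s\n",
              if (is.character(icer)) icer else sprintf("EUR %.0f", icer)))
  cat(sprintf("  NMB at EUR %s/QALY: EUR %s thousand\n",
              format(x$incremental$lambda, big.mark = ","), fmtk(x$incremental$nmb)))
  invisible(x)
}
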