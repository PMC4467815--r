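# Three-state annual-cycle Markov cohort engine: predialysis ->
# dialysis -> death, with serum-phosphorus-stratified relative risks on
# mortality and CKD progression, a 40-year cap and half-cycle
# correction. The dialysis state is internally split into response
# subgroups (each with its own drug and SP level); traces aggregate
# them back to the three reported states.

#' Adjust a baseline annual probability for a mortality relative risk
#'
#' The default `"rate"` domain converts the probability to the rate
#' scale before scaling, `p' = 1 - (1 - p)^RR`, which keeps adjusted
#' probabilities below 1 for any RR; `"multiplicative"` applies
#' `min(1, p * RR)`.
#'
#' @param base_rate Baseline annual probability in [0, 1].
#' @param rr Relative risk (> 0).
#' @param domain `"rate"` or `"multiplicative"`.
#' @return Adjusted annual probability.
#' @export
#' @examples
#' mortality_probability(0.123, 1.90) # 0.2207...
mortality_probability <- function(base_rate, rr,
                                  domain = c("rate", "multiplicative")) {
  domain <- match.arg(domain)
  stopifnot(base_rate >= 0, base_rate <= 1, rr > 0)
  if (rr == 1) return(base_rate)  # exact identity, no floating-point drift
  if (domain == "rate") 1 - (1 - base_rate)^rr else pmin(1, base_rate * rr)
}

#' Annual CKD progression probability at a serum-phosphorus level
#'
#' Progression accelerates with SP above target: the baseline annual
#' probability is adjusted by `rr_per_mgdl ^ max(0, sp - sp_target)`,
#' applied in the same domain as [mortality_probability()]. At or below
#' target the baseline applies unchanged.
#'
#' @param base_rate Baseline annual progression probability.
#' @param sp Serum phosphorus (mg/dL).
#' @param sp_target Target SP (mg/dL); 4.6 in the base case.
#' @param rr_per_mgdl Relative risk per 1 mg/dL of SP above target.
#' @inheritParams mortality_probability
#' @return Adjusted annual progression probability.
#' @export
progression_probability <- function(base_rate, sp, sp_target, rr_per_mgdl,
                                    domain = c("rate", "multiplicative")) {
  domain <- match.arg(domain)
  stopifnot(base_rate >= 0, base_rate <= 1, rr_per_mgdl > 0)
  rr <- rr_per_mgdl^max(0, sp - sp_target)
  mortality_probability(base_rate, rr, domain)
}

#' Per-cycle transition probabilities for one treatment arm
#'
#' Responders carry the representative at-target SP, non-responders the
#' stage baseline SP; mortality RRs come from the stage's strata table
#' and progression from the per-mg/dL progression risk.
#'
#' @param arm One arm from [build_arms()].
#' @param params A `phoscea_parameters` object.
#' @return A list with `p_die_pre`, `p_prog` (predialysis death and
#'   progression probabilities) and `p_die_dial`, a vector of dialysis
#'   death probabilities per dialysis subgroup of the arm's mix.
#' @export
build_transitions <- function(arm, params) {
  epi <- params$epi
  st <- params$settings
  dial_table <- params$rr_tables[[
    if (identical(st$dialysis_rr_table, "alt")) "dialysis_alt" else "dialysis"]]
  p_die_pre <- mortality_probability(
    epi$mortality_predialysis_annual,
    rr_for_sp(params$rr_tables$predialysis, arm$sp), st$rr_domain)
  p_prog <- progression_probability(
    epi$progression_annual, arm$sp, st$sp_target,
    epi$rr_progression_per_mgdl, st$rr_domain)
  p_die_dial <- vapply(arm$dialysis_mix$sp, function(sp) {
    mortality_probability(epi$mortality_dialysis_annual,
                          rr_for_sp(dial_table, sp), st$rr_domain)
  }, 0)
  list(p_die_pre = p_die_pre, p_prog = p_prog, p_die_dial = p_die_dial)
}

competing_risk_split <- function(p_die, p_prog, mode) {
  # Returns c(P(die), P(progress)) from the predialysis state in one
  # cycle. death_first evaluates death before progression so rows sum
  # to 1 without renormalization; independent_renormalized applies both
  # probabilities directly, rescaling only if they exceed 1 jointly.
  if (mode == "death_first") {
    c(die = p_die, prog = (1 - p_die) * p_prog)
  } else {
    tot <- p_die + p_prog
    if (tot > 1) c(die = p_die / tot, prog = p_prog / tot)
    else c(die = p_die, prog = p_prog)
  }
}

#' Run the cohort simulation for one treatment arm
#'
#' Iterates state occupancy (as fractions of the arm's cohort, starting
#' from full predialysis occupancy) for `horizon_years` annual cycles.
#' Death is absorbing; no return from dialysis to predialysis.
#'
#' @inheritParams build_transitions
#' @return A `phoscea_trace`: a list with `occupancy` (raw end-of-cycle
#'   matrix, rows 0..H, columns predialysis / one per dialysis subgroup
#'   / dead), `corrected` (half-cycle corrected rows 1..H), `inflow`
#'   (per-cycle arrivals into each dialysis subgroup, used for
#'   trial-on-entry costs), the arm, and `cycles`.
#' @export
run_cohort <- function(arm, params) {
  st <- params$settings
  H <- st$horizon_years
  tr <- build_transitions(arm, params)
  split <- competing_risk_split(tr$p_die_pre, tr$p_prog, st$competing_risk)
  K <- nrow(arm$dialysis_mix)
  cols <- c("predialysis", arm$dialysis_mix$subgroup, "dead")
  occ <- matrix(0, nrow = H + 1, ncol = K + 2,
                dimnames = list(0:H, cols))
  inflow <- matrix(0, nrow = H, ncol = K,
                   dimnames = list(1:H, arm$dialysis_mix$subgroup))
  occ[1, 1] <- 1
  for (t in seq_len(H)) {
    pre <- occ[t, 1]
    dial <- occ[t, 1 + seq_len(K)]
    new_dial <- pre * split["prog"] * arm$dialysis_mix$fraction
    inflow[t, ] <- new_dial
    dial_next <- dial * (1 - tr$p_die_dial) + new_dial
    pre_next <- pre * (1 - split["die"] - split["prog"])
    occ[t + 1, 1] <- pre_next
    occ[t + 1, 1 + seq_len(K)] <- dial_next
    occ[t + 1, K + 2] <- 1 - pre_next - sum(dial_next)
  }
  structure(list(occupancy = occ, corrected = half_cycle_matrix(occ),
                 inflow = inflow, arm = arm, cycles = H),
            class = "phoscea_trace")
}

half_cycle_matrix <- function(occ) {
  n <- nrow(occ)
  (occ[-n, , drop = FALSE] + occ[-1, , drop = FALSE]) / 2
}

#' Half-cycle correction of a cohort trace
#'
#' Life-table correction: the corrected occupancy for cycle t is the
#' mean of the raw end-of-cycle occupancies at t - 1 and t, crediting
#' transitions mid-cycle. All cost and QALY accumulation uses the
#' corrected occupancy.
#'
#' @param trace A `phoscea_trace` from [run_cohort()] (or any matrix
#'   with >= 2 rows).
#' @return The trace with its `corrected` component recomputed (or the
#'   corrected matrix, if a bare matrix was supplied).
#' @export
half_cycle_correct <- function(trace) {
  if (is.matrix(trace)) {
    if (nrow(trace) < 2) stop("need at least 2 occupancy rows", call. = FALSE)
    return(half_cycle_matrix(trace))
  }
  if (nrow(trace$occupancy) < 2) stop("need at least 2 occupancy rows", call. = FALSE)
  trace$corrected <- half_cycle_matrix(trace$occupancy)
  trace
}

aggregate_states <- function(m, mix) {
  # Collapse dialysis subgroup columns to the three reported states.
  K <- nrow(mix)
  cbind(predialysis = m[, 1],
        dialysis = if (K == 1) m[, 2] else rowSums(m[, 1 + seq_len(K), drop = FALSE]),
        dead = m[, K + 2])
}

#' Run all arms of one strategy
#'
#' @inheritParams build_arms
#' @return A `phoscea_strategy_run`: list with `strategy`, `arms`,
#'   `traces` (one per arm) and `trace` — the cohort-fraction-weighted
#'   aggregate occupancy over the three reported states (raw, rows
#'   0..H) plus its half-cycle-corrected counterpart.
#' @export
run_strategy <- function(params, strategy = c("cb", "lc")) {
  strategy <- match.arg(strategy)
  arms <- build_arms(params, strategy)
  traces <- lapply(arms, run_cohort, params = params)
  H <- params$settings$horizon_years
  agg <- matrix(0, H + 1, 3, dimnames = list(0:H, c("predialysis", "dialysis", "dead")))
  for (i in seq_along(arms)) {
    agg <- agg + arms[[i]]$fraction *
      aggregate_states(traces[[i]]$occupancy, arms[[i]]$dialysis_mix)
  }
  structure(list(strategy = strategy, arms = arms, traces = traces,
                 trace = agg, corrected = half_cycle_matrix(agg)),
            class = "phoscea_strategy_run")
}
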