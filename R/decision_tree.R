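`%||%` <- function(a, b) if (is.null(a)) b else a

# Initial decision tree: split the entering predialysis cohort by
# first-line calcium-binder (CB) response; under the second-line
# strategy, non-responders trial lanthanum carbonate (LC) and failures
# switch back to CB after the 8-week trial. All arithmetic is
# expected-value (fractional cohorts), matching the model's reported
# expected counts (e.g. 445 responders = 1,000 x 44.5%).

#' Split a cohort by first-line treatment response
#'
#' @param cohort_size Number (possibly fractional) of patients entering.
#' @param response_rate Probability of response in [0, 1].
#' @return A list with `responders` and `non_responders`; the two sum to
#'   `cohort_size` exactly.
#' @export
#' @examples
#' classify_first_line(1000, 0.445) # 445 / 555
classify_first_line <- function(cohort_size, response_rate) {
  stopifnot(cohort_size >= 0, response_rate >= 0, response_rate <= 1)
  r <- cohort_size * response_rate
  list(responders = r, non_responders = cohort_size - r)
}

#' Assign second-line lanthanum carbonate to first-line non-responders
#'
#' @param non_responders Count of CB non-responders.
#' @param lc_response_rate LC response probability in [0, 1].
#' @return A list with `lc_responders` and `lc_failures` (who switch
#'   back to CB after the trial period).
#' @export
assign_second_line <- function(non_responders, lc_response_rate) {
  stopifnot(non_responders >= 0, lc_response_rate >= 0, lc_response_rate <= 1)
  r <- non_responders * lc_response_rate
  list(lc_responders = r, lc_failures = non_responders - r)
}

#' First-cycle drug-cost weights for the second-line trial
#'
#' Patients who fail the LC trial incur `weeks / 52` of a year's LC cost
#' and the complement in CB cost during their first cycle on trial.
#'
#' @param lc_trial_weeks Trial duration in weeks, in [0, 52] (8 in the
#'   base case).
#' @return A list with `lc_fraction` and `cb_fraction` (summing to 1).
#' @export
lc_trial_year_cost_weight <- function(lc_trial_weeks) {
  stopifnot(lc_trial_weeks >= 0, lc_trial_weeks <= 52)
  list(lc_fraction = lc_trial_weeks / 52, cb_fraction = 1 - lc_trial_weeks / 52)
}

dialysis_mix_for <- function(params, origin = c("responder_lc", "other")) {
  # Composition of the dialysis state for patients arriving from
  # predialysis. Default: response is re-evaluated on arrival using the
  # dialysis-stage rates; with re_evaluate_on_dialysis = FALSE,
  # predialysis LC responders carry their LC response into dialysis and
  # everyone else arrives as their predialysis status dictates.
  origin <- match.arg(origin)
  ef <- params$efficacy
  st <- params$settings
  # Dialysis responders sit at the representative controlled SP; a
  # relaxed dialysis target (scenario S4) shifts it by the same margin,
  # changing only the RR-stratum assignment.
  sp_resp <- params$epi$sp_responder +
    max(0, (st$sp_target_dialysis %||% st$sp_target) - st$sp_target)
  sp_non <- params$epi$sp_nonresponder_dialysis
  mix_cb <- tibble::tibble(
    subgroup = c("d_cb_responder", "d_nonresponder_on_cb"),
    fraction = c(ef$response_rate_cb_dialysis, 1 - ef$response_rate_cb_dialysis),
    sp = c(sp_resp, sp_non), drug = c("cb", "cb"), lc_trial_on_entry = FALSE
  )
  mix_lc <- {
    p_cb <- ef$response_rate_cb_dialysis
    p_lc <- ef$response_rate_lc_dialysis
    tibble::tibble(
      subgroup = c("d_cb_responder", "d_lc_responder", "d_lc_failure"),
      fraction = c(p_cb, (1 - p_cb) * p_lc, (1 - p_cb) * (1 - p_lc)),
      sp = c(sp_resp, sp_resp, sp_non),
      drug = c("cb", "lc", "cb"),
      lc_trial_on_entry = c(FALSE, FALSE, TRUE)
    )
  }
  carry <- function(subgroup, sp, drug) {
    tibble::tibble(subgroup = subgroup, fraction = 1, sp = sp, drug = drug,
                   lc_trial_on_entry = FALSE)
  }
  strategy <- attr(params, "strategy_context")
  if (isTRUE(params$settings$re_evaluate_on_dialysis)) {
    if (identical(strategy, "lc")) mix_lc else mix_cb
  } else {
    switch(origin,
      responder_lc = carry("d_lc_responder", params$epi$sp_responder, "lc"),
      other = if (identical(strategy, "lc")) mix_lc else mix_cb
    )
  }
}

#' Build the treatment arms of one strategy
#'
#' Expands the decision tree of one strategy into predialysis arms —
#' each with its cohort fraction, representative serum phosphorus,
#' drug regimen, and whether the arm pays the 8-week LC trial cost in
#' its first cycle — plus the dialysis-arrival composition each arm
#' feeds on progression.
#'
#' Strategy `"cb"` (continued calcium binders) yields arms
#' `{cb_responder, nonresponder_on_cb}`; strategy `"lc"` (second-line
#' lanthanum carbonate) yields `{cb_responder, lc_responder,
#' lc_failure_switched_back}`.
#'
#' @param params A `phoscea_parameters` object.
#' @param strategy `"cb"` or `"lc"`.
#' @return A list of arms; each arm is a list with `subgroup`,
#'   `fraction`, `sp`, `drug`, `lc_trial_first_cycle` and a
#'   `dialysis_mix` tibble. Fractions sum to 1.
#' @export
build_arms <- function(params, strategy = c("cb", "lc")) {
  strategy <- match.arg(strategy)
  attr(params, "strategy_context") <- strategy
  ef <- params$efficacy
  fl <- classify_first_line(1, ef$response_rate_cb_predialysis)
  sp_resp <- params$epi$sp_responder
  sp_non <- params$epi$sp_nonresponder_predialysis
  arm <- function(subgroup, fraction, sp, drug, trial, origin) {
    list(subgroup = subgroup, fraction = fraction, sp = sp, drug = drug,
         lc_trial_first_cycle = trial, strategy = strategy,
         dialysis_mix = dialysis_mix_for(params, origin))
  }
  if (strategy == "cb") {
    arms <- list(
      arm("cb_responder", fl$responders, sp_resp, "cb", FALSE, "other"),
      arm("nonresponder_on_cb", fl$non_responders, sp_non, "cb", FALSE, "other")
    )
  } else {
    sl <- assign_second_line(fl$non_responders, ef$response_rate_lc_predialysis)
    arms <- list(
      arm("cb_responder", fl$responders, sp_resp, "cb", FALSE, "other"),
      arm("lc_responder", sl$lc_responders, sp_resp, "lc", FALSE, "responder_lc"),
      arm("lc_failure_switched_back", sl$lc_failures, sp_non, "cb", TRUE, "other")
    )
  }
  arms <- Filter(function(a) a$fraction > 0, arms)
  stopifnot(abs(sum(vapply(arms, `[[`, 0, "fraction")) - 1) < 1e-12)
  arms
}
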