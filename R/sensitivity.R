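# One-way scenario analyses (S1-S10) and the probabilistic sensitivity
# analysis (PSA) with cost-effectiveness acceptability curves.

#' The ten bundled one-way scenarios
#'
#' S1/S2 shorten the horizon (5/10 years); S3 includes unrelated future
#' dialysis costs in both arms; S4 raises the dialysis SP target to
#' 5 mg/dL (changing only RR-stratum assignment — response rates for
#' the relaxed target are not re-derived); S5/S6 set the discount rate
#' to 6%/0%; S7/S8 replace the averaged comparator with calcium acetate
#' / calcium carbonate alone; S9 swaps the dialysis mortality RR table
#' for the alternate published set; S10 removes the vomiting utility
#' decrement.
#'
#' @return A named list of scenarios (`id`, `description`, `apply`:
#'   a function transforming a `phoscea_parameters` object).
#' @export
scenario_definitions <- function() {
  mk <- function(id, description, apply) list(id = id, description = description, apply = apply)
  list(
    S1 = mk("S1", "Time horizon 5 years",
            function(p) { p$settings$horizon_years <- 5; p }),
    S2 = mk("S2", "Time horizon 10 years",
            function(p) { p$settings$horizon_years <- 10; p }),
    S3 = mk("S3", "Included unrelated future dialysis costs",
            function(p) { p$settings$future_dialysis_cost_mode <- "full"; p }),
    S4 = mk("S4", "Dialysis SP target level 5 mg/dL",
            function(p) { p$settings$sp_target_dialysis <- 5.0; p }),
    S5 = mk("S5", "Annual discount rate 6%",
            function(p) { p$settings$discount_rate <- 0.06; p }),
    S6 = mk("S6", "Annual discount rate 0%",
            function(p) { p$settings$discount_rate <- 0; p }),
    S7 = mk("S7", "Comparator calcium acetate only",
            function(p) { p$cb_composition <- "ca_only"; p }),
    S8 = mk("S8", "Comparator calcium carbonate only",
            function(p) { p$cb_composition <- "cc_only"; p }),
    S9 = mk("S9", "Alternate dialysis mortality RR set",
            function(p) { p$settings$dialysis_rr_table <- "alt"; p }),
    S10 = mk("S10", "Without utility decrement for vomiting",
             function(p) { p$utilities$vomit_decrement <- 0; p })
  )
}

#' Run one scenario
#'
#' @param id Scenario id, `"S1"` to `"S10"`.
#' @param base Base-case `phoscea_parameters`.
#' @return The `phoscea_ce` result of the modified run, with the
#'   scenario `id` and `description` attached.
#' @export
run_scenario <- function(id, base = default_parameters()) {
  defs <- scenario_definitions()
  if (!id %in% names(defs)) {
    stop("unknown scenario id '", id, "'; known: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  sc <- defs[[id]]
  ce <- run_ce(validate_parameters(sc$apply(unclass(base))))
  ce$scenario <- list(id = sc$id, description = sc$description)
  ce
}

#' Run a set of scenarios and tabulate them
#'
#' @param ids Scenario ids (default: all ten).
#' @param base Base-case parameters.
#' @return A tibble with one row per scenario: cohort QALYs and total
#'   costs per strategy, deltas, ICER or dominance label.
#' @export
run_scenarios <- function(ids = names(scenario_definitions()),
                          base = default_parameters()) {
  rows <- lapply(ids, function(id) {
    ce <- run_scenario(id, base)
    icer <- ce$incremental$icer_per_qaly
    tibble::tibble(
      id = id, description = ce$scenario$description,
      qalys_cb = ce$cb$qalys, qalys_lc = ce$lc$qalys,
      delta_qalys = ce$incremental$delta_qalys,
      cost_cb_thousand = ce$cb$total_cost / 1000,
      cost_lc_thousand = ce$lc$total_cost / 1000,
      delta_cost_thousand = ce$incremental$delta_cost / 1000,
      icer_per_qaly = if (is.character(icer)) NA_real_ else icer,
      dominance = ce$incremental$dominance
    )
  })
  do.call(rbind, rows)
}

lognormal_draw <- function(mean, cv) {
  # moment-matched lognormal: E = mean, CV = cv
  if (mean <= 0) return(mean)
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(1, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

normal_from_ci <- function(mean, ci_low, ci_high, floor = 1e-6) {
  # sd from the 95% CI width; inconsistent printed CIs (bounds not
  # bracketing the mean) fall back to 10% of the mean. A degenerate CI
  # (both bounds at the mean) is a point mass.
  sd <- if (!is.null(ci_low) && !is.null(ci_high) &&
            ci_low <= mean && mean <= ci_high) {
    (ci_high - ci_low) / 3.92
  } else 0.1 * mean
  if (sd == 0) return(mean)
  max(floor, stats::rnorm(1, mean, sd))
}

beta_moment_draw <- function(mean, sd) {
  if (sd <= 0) return(mean)
  v <- sd^2
  if (v >= mean * (1 - mean)) stop(
    sprintf("infeasible beta moment match for mean %g, sd %g", mean, sd),
    call. = FALSE)
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  stats::rbeta(1, a, b)
}

binomial_rate_draw <- function(rate, n) stats::rbinom(1, n, rate) / n

#' Specification of the probabilistic sensitivity analysis
#'
#' @param n_iterations Monte-Carlo iterations (1,000 in the base case).
#' @param cost_cv Coefficient of variation of the lognormal cost
#'   distributions (no dispersion is published for costs; 0.2 is a
#'   conventional default).
#' @param utility_cv Coefficient of variation used to build the beta
#'   distributions for utilities (no dispersion published; 0.1).
#' @param mortality_dialysis_cv Coefficient of variation of the normal
#'   distribution for the dialysis baseline mortality (no CI
#'   published; 0.1).
#' @param lambda_grid Willingness-to-pay grid for the CEAC (EUR/QALY).
#' @return A `phoscea_psa_spec` list.
#' @export
psa_spec <- function(n_iterations = 1000, cost_cv = 0.2, utility_cv = 0.1,
                     mortality_dialysis_cv = 0.1,
                     lambda_grid = c(0, 10000, 20000, 30000, 45000, 60000, 100000)) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = n_iterations, cost_cv = cost_cv,
                 utility_cv = utility_cv,
                 mortality_dialysis_cv = mortality_dialysis_cv,
                 lambda_grid = sort(unique(lambda_grid))),
            class = "phoscea_psa_spec")
}

#' Draw one sampled parameter set for the PSA
#'
#' Costs (pack prices, the calcium-acetate cost/g override, the annual
#' dialysis cost) are lognormal, moment-matched to their base values at
#' the spec's coefficient of variation; treatment response rates are
#' binomial draws at the source trial sizes divided by those sizes;
#' mortality relative risks (every stratum of the active tables and the
#' per-mg/dL progression risk) and the dialysis baseline mortality are
#' normal with sd from the printed 95% CI width / 3.92 (10% of the mean
#' where the printed CI is unusable), truncated above zero; utilities
#' are beta by method of moments. All other parameters stay fixed.
#'
#' @param base Base-case `phoscea_parameters`.
#' @param spec A [psa_spec()].
#' @return A validated sampled `phoscea_parameters` object. Randomness
#'   comes from the current RNG state; seed outside.
#' @export
sample_parameters <- function(base, spec = psa_spec()) {
  p <- unclass(base)
  for (d in names(p$drugs)) {
    p$drugs[[d]]$pack_price <- lognormal_draw(p$drugs[[d]]$pack_price, spec$cost_cv)
    ov <- p$drugs[[d]]$cost_per_gram_override
    if (!is.null(ov) && !is.na(ov)) {
      p$drugs[[d]]$cost_per_gram_override <- lognormal_draw(ov, spec$cost_cv)
    }
  }
  p$settings$dialysis_annual_cost <-
    lognormal_draw(p$settings$dialysis_annual_cost, spec$cost_cv)
  ef <- p$efficacy
  draw_rate <- function(rate, n) {
    r <- binomial_rate_draw(rate, n)
    min(max(r, 0), 1)
  }
  ef$response_rate_cb_predialysis <- draw_rate(ef$response_rate_cb_predialysis, ef$n_trial_cb_pre)
  ef$response_rate_lc_predialysis <- draw_rate(ef$response_rate_lc_predialysis, ef$n_trial_lc_pre)
  ef$response_rate_cb_dialysis <- draw_rate(ef$response_rate_cb_dialysis, ef$n_trial_cb_dial)
  ef$response_rate_lc_dialysis <- draw_rate(ef$response_rate_lc_dialysis, ef$n_trial_lc_dial)
  # keep CIs bracketing the sampled points so validation passes
  ef$ci_cb_predialysis <- range(ef$ci_cb_predialysis, ef$response_rate_cb_predialysis)
  ef$ci_lc_predialysis <- range(ef$ci_lc_predialysis, ef$response_rate_lc_predialysis)
  ef$ci_cb_dialysis <- range(ef$ci_cb_dialysis, ef$response_rate_cb_dialysis)
  ef$ci_lc_dialysis <- range(ef$ci_lc_dialysis, ef$response_rate_lc_dialysis)
  p$efficacy <- ef
  for (nm in names(p$rr_tables)) {
    tb <- p$rr_tables[[nm]]
    for (i in seq_len(nrow(tb))) {
      tb$rr[i] <- normal_from_ci(tb$rr[i], tb$ci_low[i], tb$ci_high[i])
      tb$ci_low[i] <- min(tb$ci_low[i], tb$rr[i])
      tb$ci_high[i] <- max(tb$ci_high[i], tb$rr[i])
    }
    # preserve the non-decreasing step structure of the published tables
    tb$rr <- cummax(tb$rr)
    tb$ci_high <- pmax(tb$ci_high, tb$rr)
    p$rr_tables[[nm]] <- tb
  }
  epi <- p$epi
  epi$mortality_dialysis_annual <- min(1, max(1e-6, stats::rnorm(
    1, epi$mortality_dialysis_annual,
    spec$mortality_dialysis_cv * epi$mortality_dialysis_annual)))
  epi$rr_progression_per_mgdl <- normal_from_ci(
    epi$rr_progression_per_mgdl,
    epi$ci_rr_progression[1], epi$ci_rr_progression[2])
  epi$ci_rr_progression <- range(epi$ci_rr_progression, epi$rr_progression_per_mgdl)
  p$epi <- epi
  ut <- p$utilities
  ut$utility_predialysis <- beta_moment_draw(
    ut$utility_predialysis, spec$utility_cv * ut$utility_predialysis)
  ut$utility_dialysis <- beta_moment_draw(
    ut$utility_dialysis, spec$utility_cv * ut$utility_dialysis)
  p$utilities <- ut
  validate_parameters(p)
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeats the full pipeline on jointly sampled parameter sets and
#' summarizes the cloud of incremental points on the
#' cost-effectiveness plane.
#'
#' @param base Base-case `phoscea_parameters`.
#' @param spec A [psa_spec()].
#' @param seed Integer seed; identical seeds give identical results.
#' @return A `phoscea_psa` list: `points` (tibble of iteration,
#'   `delta_cost`, `delta_qalys`, `dominant`), `fraction_dominant`,
#'   `ceac` (tibble of `lambda`, `fraction_cost_effective` under the
#'   NMB > 0 criterion), `spec`, `seed`.
#' @export
run_psa <- function(base = default_parameters(), spec = psa_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$n_iterations
  dC <- dQ <- numeric(n)
  for (i in seq_len(n)) {
    ce <- run_ce(sample_parameters(base, spec))
    dC[i] <- ce$incremental$delta_cost
    dQ[i] <- ce$incremental$delta_qalys
  }
  points <- tibble::tibble(iteration = seq_len(n), delta_cost = dC,
                           delta_qalys = dQ, dominant = dC < 0 & dQ > 0)
  ceac <- tibble::tibble(
    lambda = spec$lambda_grid,
    fraction_cost_effective = vapply(spec$lambda_grid,
                                     function(l) mean(l * dQ - dC > 0), 0))
  structure(list(points = points, fraction_dominant = mean(points$dominant),
                 ceac = ceac, spec = spec, seed = seed),
            class = "phoscea_psa")
}

#' @export
print.phoscea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", nrow(x$points), x$seed))
  cat(sprintf("  LC dominant in %.1f%% of iterations\n", 100 * x$fraction_dominant))
  at30 <- x$ceac$fraction_cost_effective[x$ceac$lambda == 30000]
  if (length(at30)) {
    cat(sprintf("  cost-effective at EUR 30,000/QALY: %.1f%%\n", 100 * at30))
  }
  invisible(x)
}
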