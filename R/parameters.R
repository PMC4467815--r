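#' @title Model parameters for the phosphate-binder cost-effectiveness model
#'
#' @description
#' A `phoscea_parameters` object is a validated list with components
#' `drugs`, `efficacy`, `epi`, `rr_tables`, `utilities`, `settings` and
#' `cb_composition`, covering every input of the decision-tree + Markov
#' model: drug pack prices and doses, first/second-line response rates,
#' baseline mortality and CKD progression, serum-phosphorus (SP)
#' stratified mortality relative risks, health-state utilities, and run
#' settings (cohort size, horizon, discount rate, willingness-to-pay
#' threshold, costing mode).
#'
#' Monetary values are euros (2013); SP concentrations are mg/dL; cycle
#' length is one year.
#' @name phoscea_parameters
NULL

# Relative-risk tables: lower-inclusive, upper-exclusive strata covering
# (0, Inf). The predialysis strata >= 5.5 mg/dL share a flat RR of 1.90
# whose printed interval (1.10-1.29) does not bracket it; it is stored
# as printed and flagged so the PSA falls back to a 10%-of-mean sd.
rr_table_predialysis <- function() {
  tibble::tibble(
    sp_low  = c(0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 7.0, 8.0, 9.0),
    sp_high = c(2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 7.0, 8.0, 9.0, Inf),
    rr      = c(0.95, 1.00, 1.15, 1.32, 1.34, 1.83, 1.90, 1.90, 1.90, 1.90, 1.90, 1.90),
    ci_low  = c(0.69, 1.00, 0.95, 1.09, 1.05, 1.33, 1.30, 1.10, 1.10, 1.10, 1.10, 1.10),
    ci_high = c(1.32, 1.00, 1.39, 1.61, 1.71, 2.51, 2.79, 1.29, 1.29, 1.29, 1.29, 1.29)
  )
}

rr_table_dialysis <- function() {
  tibble::tibble(
    sp_low  = c(0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 7.0, 8.0, 9.0),
    sp_high = c(2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 7.0, 8.0, 9.0, Inf),
    rr      = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.07, 1.07, 1.25, 1.43, 1.67, 2.02),
    ci_low  = c(0.96, 0.96, 0.93, 0.93, 1.00, 1.00, 1.01, 1.01, 1.17, 1.31, 1.51, 1.76),
    ci_high = c(1.24, 1.24, 1.07, 1.07, 1.00, 1.00, 1.14, 1.14, 1.34, 1.54, 1.86, 2.27)
  )
}

# Alternate dialysis RR set (Block 1998), used by scenario S9 only. The
# source prints non-contiguous bands (1.02 covers 5.5-6.5 mg/dL, 1.18
# covers 6.6-7.8); stored as contiguous strata so coverage holds.
rr_table_dialysis_alt <- function() {
  tibble::tibble(
    sp_low  = c(0, 4.5, 5.5, 6.5, 8.0),
    sp_high = c(4.5, 5.5, 6.5, 8.0, Inf),
    rr      = c(1.00, 1.00, 1.02, 1.18, 1.39),
    ci_low  = c(0.87, 1.00, 0.89, 1.02, 1.21),
    ci_high = c(1.15, 1.00, 1.17, 1.36, 1.60)
  )
}

#' Default (base-case) model parameters
#'
#' Returns the bundled base-case parameter set: a 1,000-patient
#' predialysis cohort followed for up to 40 annual cycles at a 3%
#' discount rate, drug costs from 2013 Spanish ex-factory prices net of
#' the 7.5% mandatory rebate, SP-stratified mortality relative risks,
#' and trial-derived response rates for calcium binders (CB) and
#' lanthanum carbonate (LC).
#'
#' The dialysis baseline annual mortality is not an externally published
#' input of this model; the bundled value is obtained by one-dimensional
#' calibration of the continued-CB arm's discounted life expectancy
#' (see [calibrate_dialysis_mortality()] and `analysis/01_calibration.R`).
#'
#' @return A validated `phoscea_parameters` object.
#' @export
#' @examples
#' p <- default_parameters()
#' cb_annual_cost(p, "predialysis") # ~ EUR 49 / year
default_parameters <- function() {
  p <- list(
    drugs = list(
      lc = list(
        name = "lanthanum carbonate", mg_per_tablet = 750,
        tablets_per_pack = 90, pack_price = 167.86,
        rebate_applied = TRUE, cost_per_gram_override = NA_real_,
        daily_dose_predialysis = 1875, daily_dose_dialysis = 2250
      ),
      cc = list(
        name = "calcium carbonate", mg_per_tablet = 1250,
        tablets_per_pack = 60, pack_price = 2.09,
        rebate_applied = TRUE, cost_per_gram_override = NA_real_,
        daily_dose_predialysis = 3000, daily_dose_dialysis = 5000
      ),
      ca = list(
        name = "calcium acetate", mg_per_tablet = 1250,
        tablets_per_pack = 60, pack_price = 7.13,
        rebate_applied = TRUE,
        # Printed cost/g (EUR 0.124) and annual costs (EUR 68 / 136) are
        # internally consistent with each other but not with the pack
        # arithmetic (7.13 / 75 g = 0.095); the printed figures win.
        cost_per_gram_override = 0.124,
        daily_dose_predialysis = 1500, daily_dose_dialysis = 3000
      )
    ),
    efficacy = list(
      response_rate_cb_predialysis = 0.445, ci_cb_predialysis = c(0.321, 0.571),
      response_rate_lc_predialysis = 0.383, ci_lc_predialysis = c(0.327, 0.440),
      response_rate_cb_dialysis    = 0.341, ci_cb_dialysis    = c(0.310, 0.374),
      response_rate_lc_dialysis    = 0.166, ci_lc_dialysis    = c(0.135, 0.199),
      n_trial_cb_pre = 28, n_trial_lc_pre = 56,
      n_trial_cb_dial = 123, n_trial_lc_dial = 257
    ),
    epi = list(
      mortality_predialysis_annual = 0.123,
      # calibration output; see calibrate_dialysis_mortality() and
      # analysis/01_calibration.R, which records this value
      mortality_dialysis_annual = 0.044051,
      progression_annual = 0.143, ci_progression = c(0.136, 0.150),
      rr_progression_per_mgdl = 1.19, ci_rr_progression = c(1.10, 1.29),
      sp_nonresponder_predialysis = 5.7,
      sp_nonresponder_dialysis = 6.0,
      sp_responder = 4.0
    ),
    rr_tables = list(
      predialysis = rr_table_predialysis(),
      dialysis = rr_table_dialysis(),
      dialysis_alt = rr_table_dialysis_alt()
    ),
    utilities = list(
      utility_predialysis = 0.71, utility_dialysis = 0.61,
      vomit_decrement = 0.04082,
      vomit_rate_lc_predialysis = 0.040, vomit_rate_lc_dialysis = 0.072
    ),
    settings = list(
      cohort_size = 1000, horizon_years = 40, discount_rate = 0.03,
      days_per_year = 365, threshold_lambda = 30000,
      sp_target = 4.6, sp_target_dialysis = 4.6,
      sp_initiation_predialysis = 4.6, sp_initiation_dialysis = 5.5,
      future_dialysis_cost_mode = "attributable_only",
      dialysis_annual_cost = 42556, rebate_fraction = 0.075,
      lc_trial_weeks = 8,
      re_evaluate_on_dialysis = TRUE,
      rr_domain = "rate",              # or "multiplicative"
      competing_risk = "death_first",  # or "independent_renormalized"
      discount_timing = "half_cycle",  # or "end_cycle"
      seed = 1L
    ),
    cb_composition = "average"
  )
  validate_parameters(p)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a structured YAML file mirroring the `phoscea_parameters`
#' layout (see the bundled `inst/extdata/params_basecase.yaml` for the
#' canonical, fully commented schema), coerces the relative-risk tables
#' to data frames and validates every invariant.
#'
#' @param config_path Path to a YAML parameter file.
#' @return A validated `phoscea_parameters` object.
#' @export
load_parameters <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("parameter file not found: ", config_path, call. = FALSE)
  }
  raw <- yaml::read_yaml(config_path)
  for (nm in names(raw$rr_tables)) {
    tb <- raw$rr_tables[[nm]]
    tb <- tibble::as_tibble(lapply(as.data.frame(do.call(
      rbind, lapply(tb, function(r) {
        unlist(r[c("sp_low", "sp_high", "rr", "ci_low", "ci_high")])
      })
    )), as.numeric))
    tb$sp_high[is.na(tb$sp_high)] <- Inf
    raw$rr_tables[[nm]] <- tb
  }
  for (fld in c("ci_cb_predialysis", "ci_lc_predialysis",
                "ci_cb_dialysis", "ci_lc_dialysis")) {
    raw$efficacy[[fld]] <- as.numeric(unlist(raw$efficacy[[fld]]))
  }
  raw$epi$ci_progression <- as.numeric(unlist(raw$epi$ci_progression))
  raw$epi$ci_rr_progression <- as.numeric(unlist(raw$epi$ci_rr_progression))
  for (d in names(raw$drugs)) {
    if (is.null(raw$drugs[[d]]$cost_per_gram_override)) {
      raw$drugs[[d]]$cost_per_gram_override <- NA_real_
    }
  }
  validate_parameters(raw)
}

#' Serialize model parameters to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p` exactly (up to the class attribute).
#'
#' @param params A `phoscea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  p <- unclass(params)
  for (nm in names(p$rr_tables)) {
    tb <- as.data.frame(p$rr_tables[[nm]])
    tb$sp_high[is.infinite(tb$sp_high)] <- NA_real_ # YAML-safe; Inf on reload
    p$rr_tables[[nm]] <- lapply(seq_len(nrow(tb)), function(i) as.list(tb[i, ]))
  }
  yaml::write_yaml(p, path, precision = 15)
  invisible(path)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, field) {
  if (is.null(x) || length(x) != 1 || is.na(x)) {
    stopf("missing required field '%s'", field)
  }
  if (x < 0 || x > 1) {
    stopf("field '%s' = %g outside [0, 1]", field, x)
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (is.null(x) || length(x) != 1 || is.na(x)) {
    stopf("missing required field '%s'", field)
  }
  if (x < 0) stopf("field '%s' = %g must be >= 0", field, x)
  invisible(x)
}

validate_rr_table <- function(tb, name) {
  if (any(tb$sp_low >= tb$sp_high)) {
    stopf("rr_tables$%s: sp_low must be < sp_high in every stratum", name)
  }
  o <- order(tb$sp_low)
  tb <- tb[o, ]
  if (tb$sp_low[1] != 0 || !is.infinite(tb$sp_high[nrow(tb)]) ||
      any(abs(tb$sp_high[-nrow(tb)] - tb$sp_low[-1]) > 1e-12)) {
    stopf("rr_tables$%s: strata must tile (0, Inf) without gaps or overlap", name)
  }
  if (any(tb$rr <= 0)) stopf("rr_tables$%s: all rr must be > 0", name)
  # The flat predialysis tail prints CI (1.10-1.29) around RR 1.90: a
  # documented source inconsistency, exempted from the bracketing check.
  inconsistent <- tb$ci_low > tb$rr | tb$ci_high < tb$rr
  known <- abs(tb$rr - 1.90) < 1e-9 & abs(tb$ci_high - 1.29) < 1e-9
  if (any(inconsistent & !known)) {
    stopf("rr_tables$%s: confidence bounds must bracket rr", name)
  }
  tb
}

#' Validate a model-parameter list
#'
#' Checks every invariant of the parameter set (probability bounds,
#' non-negative monies and doses, CI bracketing, RR-strata coverage,
#' enum values) and returns the object classed `phoscea_parameters`.
#' Error messages name the offending field and bound. A configuration
#' that omits the dialysis baseline mortality — a value that must be
#' supplied or calibrated, not assumed — fails with a message naming
#' `mortality_dialysis_annual`.
#'
#' @param params A parameter list in the layout of [default_parameters()].
#' @return The validated object, classed `phoscea_parameters`.
#' @export
validate_parameters <- function(params) {
  for (comp in c("drugs", "efficacy", "epi", "rr_tables", "utilities", "settings")) {
    if (is.null(params[[comp]])) stopf("missing required section '%s'", comp)
  }
  for (d in c("lc", "cc", "ca")) {
    dr <- params$drugs[[d]]
    if (is.null(dr)) stopf("missing drug specification '%s'", d)
    check_nonneg(dr$pack_price, paste0("drugs$", d, "$pack_price"))
    for (f in c("mg_per_tablet", "tablets_per_pack")) {
      if (check_nonneg(dr[[f]], paste0("drugs$", d, "$", f)) == 0) {
        stopf("field 'drugs$%s$%s' must be > 0", d, f)
      }
    }
    check_nonneg(dr$daily_dose_predialysis, paste0("drugs$", d, "$daily_dose_predialysis"))
    check_nonneg(dr$daily_dose_dialysis, paste0("drugs$", d, "$daily_dose_dialysis"))
  }
  ef <- params$efficacy
  for (f in c("response_rate_cb_predialysis", "response_rate_lc_predialysis",
              "response_rate_cb_dialysis", "response_rate_lc_dialysis")) {
    check_prob(ef[[f]], paste0("efficacy$", f))
  }
  for (arm in c("cb_predialysis", "lc_predialysis", "cb_dialysis", "lc_dialysis")) {
    ci <- ef[[paste0("ci_", arm)]]
    pt <- ef[[paste0("response_rate_", arm)]]
    if (length(ci) != 2 || ci[1] > pt || ci[2] < pt) {
      stopf("efficacy$ci_%s must bracket the point estimate %g", arm, pt)
    }
  }
  for (f in c("n_trial_cb_pre", "n_trial_lc_pre", "n_trial_cb_dial", "n_trial_lc_dial")) {
    if (check_nonneg(ef[[f]], paste0("efficacy$", f)) == 0) {
      stopf("field 'efficacy$%s' must be > 0", f)
    }
  }
  epi <- params$epi
  check_prob(epi$mortality_predialysis_annual, "epi$mortality_predialysis_annual")
  if (is.null(epi$mortality_dialysis_annual) || is.na(epi$mortality_dialysis_annual)) {
    stopf(paste0(
      "missing required field 'epi$mortality_dialysis_annual': the dialysis ",
      "baseline annual mortality is not a published model input and must be ",
      "supplied (see calibrate_dialysis_mortality())"))
  }
  check_prob(epi$mortality_dialysis_annual, "epi$mortality_dialysis_annual")
  check_prob(epi$progression_annual, "epi$progression_annual")
  if (check_nonneg(epi$rr_progression_per_mgdl, "epi$rr_progression_per_mgdl") == 0) {
    stopf("field 'epi$rr_progression_per_mgdl' must be > 0")
  }
  for (f in c("sp_nonresponder_predialysis", "sp_nonresponder_dialysis", "sp_responder")) {
    if (check_nonneg(epi[[f]], paste0("epi$", f)) == 0) {
      stopf("field 'epi$%s' must be > 0", f)
    }
  }
  for (nm in c("predialysis", "dialysis", "dialysis_alt")) {
    if (is.null(params$rr_tables[[nm]])) stopf("missing rr_tables$%s", nm)
    params$rr_tables[[nm]] <-
      validate_rr_table(tibble::as_tibble(params$rr_tables[[nm]]), nm)
  }
  ut <- params$utilities
  check_prob(ut$utility_predialysis, "utilities$utility_predialysis")
  check_prob(ut$utility_dialysis, "utilities$utility_dialysis")
  check_nonneg(ut$vomit_decrement, "utilities$vomit_decrement")
  check_prob(ut$vomit_rate_lc_predialysis, "utilities$vomit_rate_lc_predialysis")
  check_prob(ut$vomit_rate_lc_dialysis, "utilities$vomit_rate_lc_dialysis")
  st <- params$settings
  if (check_nonneg(st$cohort_size, "settings$cohort_size") < 1) {
    stopf("field 'settings$cohort_size' must be >= 1")
  }
  if (check_nonneg(st$horizon_years, "settings$horizon_years") < 1 ||
      st$horizon_years > 40) {
    stopf("field 'settings$horizon_years' = %g outside [1, 40]", st$horizon_years)
  }
  check_nonneg(st$discount_rate, "settings$discount_rate")
  check_nonneg(st$days_per_year, "settings$days_per_year")
  check_nonneg(st$threshold_lambda, "settings$threshold_lambda")
  check_nonneg(st$dialysis_annual_cost, "settings$dialysis_annual_cost")
  if (is.null(st$rebate_fraction) || st$rebate_fraction < 0 || st$rebate_fraction >= 1) {
    stopf("field 'settings$rebate_fraction' must be in [0, 1)")
  }
  if (st$lc_trial_weeks < 0 || st$lc_trial_weeks > 52) {
    stopf("field 'settings$lc_trial_weeks' = %g outside [0, 52]", st$lc_trial_weeks)
  }
  match_enum <- function(x, field, choices) {
    if (is.null(x) || !x %in% choices) {
      stopf("field '%s' must be one of: %s", field, paste(choices, collapse = ", "))
    }
  }
  match_enum(st$future_dialysis_cost_mode, "settings$future_dialysis_cost_mode",
             c("attributable_only", "full"))
  match_enum(st$rr_domain, "settings$rr_domain", c("rate", "multiplicative"))
  match_enum(st$competing_risk, "settings$competing_risk",
             c("death_first", "independent_renormalized"))
  match_enum(st$discount_timing, "settings$discount_timing",
             c("half_cycle", "end_cycle"))
  if (is.null(params$cb_composition)) params$cb_composition <- "average"
  match_enum(params$cb_composition, "cb_composition",
             c("average", "cc_only", "ca_only"))
  structure(params, class = "phoscea_parameters")
}

#' @export
print.phoscea_parameters <- function(x, ...) {
  st <- x$settings
  cat("phoscea model parameters\n")
  cat(sprintf("  cohort %d, horizon %d y, discount %.1f%%, lambda EUR %s/QALY\n",
              st$cohort_size, st$horizon_years, 100 * st$discount_rate,
              format(st$threshold_lambda, big.mark = ",")))
  cat(sprintf("  CB response %.1f%% / %.1f%% (pre/dial), LC %.1f%% / %.1f%%\n",
              100 * x$efficacy$response_rate_cb_predialysis,
              100 * x$efficacy$response_rate_cb_dialysis,
              100 * x$efficacy$response_rate_lc_predialysis,
              100 * x$efficacy$response_rate_lc_dialysis))
  cat(sprintf("  dialysis cost EUR %s/y, future costs: %s, CB composition: %s\n",
              format(st$dialysis_annual_cost, big.mark = ","),
              st$future_dialysis_cost_mode, x$cb_composition))
  invisible(x)
}

#' Apply the mandatory price rebate to an ex-factory price
#'
#' @param ex_factory_price Price in EUR (>= 0).
#' @param rebate_fraction Rebate as a fraction in [0, 1); the Spanish
#'   mandatory deduction is 0.075.
#' @return `ex_factory_price * (1 - rebate_fraction)`.
#' @export
#' @examples
#' apply_rebate(100, 0.075) # 92.5
apply_rebate <- function(ex_factory_price, rebate_fraction) {
  if (any(ex_factory_price < 0)) stop("ex_factory_price must be >= 0", call. = FALSE)
  if (any(rebate_fraction < 0 | rebate_fraction >= 1)) {
    stop("rebate_fraction must be in [0, 1)", call. = FALSE)
  }
  ex_factory_price * (1 - rebate_fraction)
}

#' Drug cost per gram from pack arithmetic
#'
#' @param pack_price Pack price in EUR (rebate-inclusive).
#' @param tablets_per_pack,mg_per_tablet Pack composition (> 0).
#' @return Cost in EUR per gram, unrounded.
#' @export
#' @examples
#' cost_per_gram(167.86, 90, 750) # 2.4868...
cost_per_gram <- function(pack_price, tablets_per_pack, mg_per_tablet) {
  if (any(tablets_per_pack <= 0) || any(mg_per_tablet <= 0)) {
    stop("tablets_per_pack and mg_per_tablet must be > 0", call. = FALSE)
  }
  pack_price / (tablets_per_pack * mg_per_tablet / 1000)
}

#' Annual drug cost from a daily dose
#'
#' @param daily_dose Daily dose in mg/day.
#' @param cost_per_gram Cost in EUR per gram.
#' @param days_per_year Days per year (365 in the base case).
#' @return Annual cost in EUR/year, unrounded.
#' @export
annual_drug_cost <- function(daily_dose, cost_per_gram, days_per_year = 365) {
  if (any(daily_dose < 0) || any(cost_per_gram < 0) || any(days_per_year < 0)) {
    stop("annual_drug_cost inputs must be >= 0", call. = FALSE)
  }
  daily_dose / 1000 * days_per_year * cost_per_gram
}

#' Cost per gram of one configured drug
#'
#' Uses the explicit `cost_per_gram_override` when the configuration
#' supplies one (calcium acetate in the base case, whose printed cost/g
#' is not reproducible from its pack arithmetic), otherwise derives it
#' from the pack price.
#'
#' @param params A `phoscea_parameters` object.
#' @param drug One of `"lc"`, `"cc"`, `"ca"`.
#' @return EUR per gram.
#' @export
drug_cost_per_gram <- function(params, drug) {
  dr <- params$drugs[[drug]]
  if (is.null(dr)) stopf("unknown drug '%s'", drug)
  if (!is.null(dr$cost_per_gram_override) && !is.na(dr$cost_per_gram_override)) {
    return(dr$cost_per_gram_override)
  }
  cost_per_gram(dr$pack_price, dr$tablets_per_pack, dr$mg_per_tablet)
}

#' Annual treatment cost of one configured drug at one disease stage
#'
#' @inheritParams drug_cost_per_gram
#' @param stage `"predialysis"` or `"dialysis"`.
#' @return EUR per year, unrounded.
#' @export
#' @examples
#' drug_annual_cost(default_parameters(), "lc", "predialysis") # ~1702
drug_annual_cost <- function(params, drug, stage = c("predialysis", "dialysis")) {
  stage <- match.arg(stage)
  dr <- params$drugs[[drug]]
  if (is.null(dr)) stopf("unknown drug '%s'", drug)
  dose <- if (stage == "predialysis") dr$daily_dose_predialysis else dr$daily_dose_dialysis
  annual_drug_cost(dose, drug_cost_per_gram(params, drug),
                   params$settings$days_per_year)
}

#' Annual cost of the calcium-binder comparator
#'
#' Under the default `cb_composition = "average"` the comparator is the
#' arithmetic mean of the calcium carbonate and calcium acetate annual
#' costs at the given stage; `cc_only` / `ca_only` (scenarios S8 / S7)
#' return a single drug's cost.
#'
#' @inheritParams drug_annual_cost
#' @return EUR per year, unrounded.
#' @export
cb_annual_cost <- function(params, stage = c("predialysis", "dialysis")) {
  stage <- match.arg(stage)
  switch(params$cb_composition,
    average = (drug_annual_cost(params, "cc", stage) +
               drug_annual_cost(params, "ca", stage)) / 2,
    cc_only = drug_annual_cost(params, "cc", stage),
    ca_only = drug_annual_cost(params, "ca", stage)
  )
}

#' Look up the mortality relative risk for a serum-phosphorus level
#'
#' Strata are lower-inclusive, upper-exclusive; the open end strata
#' ("<2.5", ">9.0") extend to 0 and infinity. The step function is
#' non-decreasing in SP for each bundled table.
#'
#' @param table An RR strata data frame (`sp_low`, `sp_high`, `rr`, ...).
#' @param sp Serum phosphorus in mg/dL (> 0).
#' @return The relative risk of the stratum containing `sp`.
#' @export
#' @examples
#' rr_for_sp(default_parameters()$rr_tables$predialysis, 4.7) # 1.83
rr_for_sp <- function(table, sp) {
  if (length(sp) != 1 || is.na(sp) || sp <= 0) {
    stop("sp must be a single value > 0", call. = FALSE)
  }
  hit <- which(table$sp_low <= sp & sp < table$sp_high)
  if (length(hit) != 1) stopf("sp = %g not covered by exactly one stratum", sp)
  table$rr[hit]
}
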