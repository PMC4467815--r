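# Base-case parameter set for the phoscea model (EUR, 2013 values).
# Serum phosphorus (SP) in mg/dL; cycle length one year.
# drugs: pack prices are ex-factory net of the 7.5% mandatory rebate
#   (rebate_applied: yes); cost_per_gram_override, when set, replaces the
#   pack-derived cost/g (calcium acetate: the printed EUR 0.124/g).
# efficacy: trial response rates with 95% CIs and source trial sizes.
# epi: annual baseline mortality (predialysis published; dialysis value is
#   the output of calibrate_dialysis_mortality(), see analysis/01),
#   annual progression, progression RR per mg/dL SP above target, and
#   representative SP per response subgroup.
# rr_tables: SP-stratified mortality relative risks (lower-inclusive,
#   upper-exclusive strata; sp_high .na -> open-ended).
# settings: run controls; future_dialysis_cost_mode attributable_only|full,
#   rr_domain rate|multiplicative, competing_risk death_first|independent_renormalized,
#   discount_timing half_cycle|end_cycle.

drugs:
  lc:
    name: lanthanum carbonate
    mg_per_tablet: 750.0
    tablets_per_pack: 90.0
    pack_price: 167.860000000000014
    rebate_applied: yes
    cost_per_gram_override: .na.real
    daily_dose_predialysis: 1875.0
    daily_dose_dialysis: 2250.0
  cc:
    name: calcium carbonate
    mg_per_tablet: 1250.0
    tablets_per_pack: 60.0
    pack_price: 2.09
    rebate_applied: yes
    cost_per_gram_override: .na.real
    daily_dose_predialysis: 3000.0
    daily_dose_dialysis: 5000.0
  ca:
    name: calcium acetate
    mg_per_tablet: 1250.0
    tablets_per_pack: 60.0
    pack_price: 7.13
    rebate_applied: yes
    cost_per_gram_override: 0.124
    daily_dose_predialysis: 1500.0
    daily_dose_dialysis: 3000.0
efficacy:
  response_rate_cb_predialysis: 0.445
  ci_cb_predialysis:
  - 0.321
  - 0.571
  response_rate_lc_predialysis: 0.383
  ci_lc_predialysis:
  - 0.327
  - 0.44
  response_rate_cb_dialysis: 0.341
  ci_cb_dialysis:
  - 0.31
  - 0.374
  response_rate_lc_dialysis: 0.166
  ci_lc_dialysis:
  - 0.135
  - 0.199
  n_trial_cb_pre: 28.0
  n_trial_lc_pre: 56.0
  n_trial_cb_dial: 123.0
  n_trial_lc_dial: 257.0
epi:
  mortality_predialysis_annual: 0.123
  mortality_dialysis_annual: 0.044051
  progression_annual: 0.143
  ci_progression:
  - 0.136
  - 0.15
  rr_progression_per_mgdl: 1.19
  ci_rr_progression:
  - 1.1
  - 1.29
  sp_nonresponder_predialysis: 5.7
  sp_nonresponder_dialysis: 6.0
  sp_responder: 4.0
rr_tables:
  predialysis:
  - sp_low: 0.0
    sp_high: 2.5
    rr: 0.95
    ci_low: 0.69
    ci_high: 1.32
  - sp_low: 2.5
    sp_high: 3.0
    rr: 1.0
    ci_low: 1.0
    ci_high: 1.0
  - sp_low: 3.0
    sp_high: 3.5
    rr: 1.15
    ci_low: 0.95
    ci_high: 1.39
  - sp_low: 3.5
    sp_high: 4.0
    rr: 1.32
    ci_low: 1.09
    ci_high: 1.61
  - sp_low: 4.0
    sp_high: 4.5
    rr: 1.34
    ci_low: 1.05
    ci_high: 1.71
  - sp_low: 4.5
    sp_high: 5.0
    rr: 1.83
    ci_low: 1.33
    ci_high: 2.51
  - sp_low: 5.0
    sp_high: 5.5
    rr: 1.9
    ci_low: 1.3
    ci_high: 2.79
  - sp_low: 5.5
    sp_high: 6.0
    rr: 1.9
    ci_low: 1.1
    ci_high: 1.29
  - sp_low: 6.0
    sp_high: 7.0
    rr: 1.9
    ci_low: 1.1
    ci_high: 1.29
  - sp_low: 7.0
    sp_high: 8.0
    rr: 1.9
    ci_low: 1.1
    ci_high: 1.29
  - sp_low: 8.0
    sp_high: 9.0
    rr: 1.9
    ci_low: 1.1
    ci_high: 1.29
  - sp_low: 9.0
    sp_high: .na.real
    rr: 1.9
    ci_low: 1.1
    ci_high: 1.29
  dialysis:
  - sp_low: 0.0
    sp_high: 2.5
    rr: 1.0
    ci_low: 0.96
    ci_high: 1.24
  - sp_low: 2.5
    sp_high: 3.0
    rr: 1.0
    ci_low: 0.96
    ci_high: 1.24
  - sp_low: 3.0
    sp_high: 3.5
    rr: 1.0
    ci_low: 0.93
    ci_high: 1.07
  - sp_low: 3.5
    sp_high: 4.0
    rr: 1.0
    ci_low: 0.93
    ci_high: 1.07
  - sp_low: 4.0
    sp_high: 4.5
    rr: 1.0
    ci_low: 1.0
    ci_high: 1.0
  - sp_low: 4.5
    sp_high: 5.0
    rr: 1.0
    ci_low: 1.0
    ci_high: 1.0
  - sp_low: 5.0
    sp_high: 5.5
    rr: 1.07
    ci_low: 1.01
    ci_high: 1.14
  - sp_low: 5.5
    sp_high: 6.0
    rr: 1.07
    ci_low: 1.01
    ci_high: 1.14
  - sp_low: 6.0
    sp_high: 7.0
    rr: 1.25
    ci_low: 1.17
    ci_high: 1.34
  - sp_low: 7.0
    sp_high: 8.0
    rr: 1.43
    ci_low: 1.31
    ci_high: 1.54
  - sp_low: 8.0
    sp_high: 9.0
    rr: 1.67
    ci_low: 1.51
    ci_high: 1.86
  - sp_low: 9.0
    sp_high: .na.real
    rr: 2.02
    ci_low: 1.76
    ci_high: 2.27
  dialysis_alt:
  - sp_low: 0.0
    sp_high: 4.5
    rr: 1.0
    ci_low: 0.87
    ci_high: 1.15
  - sp_low: 4.5
    sp_high: 5.5
    rr: 1.0
    ci_low: 1.0
    ci_high: 1.0
  - sp_low: 5.5
    sp_high: 6.5
    rr: 1.02
    ci_low: 0.89
    ci_high: 1.17
  - sp_low: 6.5
    sp_high: 8.0
    rr: 1.18
    ci_low: 1.02
    ci_high: 1.36
  - sp_low: 8.0
    sp_high: .na.real
    rr: 1.39
    ci_low: 1.21
    ci_high: 1.6
utilities:
  utility_predialysis: 0.71
  utility_dialysis: 0.61
  vomit_decrement: 0.04082
  vomit_rate_lc_predialysis: 0.04
  vomit_rate_lc_dialysis: 0.072
settings:
  cohort_size: 1000.0
  horizon_years: 40.0
  discount_rate: 0.03
  days_per_year: 365.0
  threshold_lambda: 30000.0
  sp_target: 4.6
  sp_target_dialysis: 4.6
  sp_initiation_predialysis: 4.6
  sp_initiation_dialysis: 5.5
  future_dialysis_cost_mode: attributable_only
  dialysis_annual_cost: 42556.0
  rebate_fraction: 0.075
  lc_trial_weeks: 8.0
  re_evaluate_on_dialysis: yes
  rr_domain: rate
  competing_risk: death_first
  discount_timing: half_cycle
  seed: 1
cb_composition: average
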