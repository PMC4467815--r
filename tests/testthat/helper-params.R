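# Shared fixtures: one base parameter set per test run, plus a tweak
# helper so tests can perturb a single field and re-validate.

base_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_parameters()
    cache
  }
})

tweak_params <- function(params, fn) {
  p <- unclass(params)
  validate_parameters(fn(p))
}

# flatten all RR tables to 1 and put every subgroup at the SP target, so
# transitions equal base rates
flat_risk_params <- function(params = base_params()) {
  tweak_params(params, function(p) {
    for (nm in names(p$rr_tables)) {
      p$rr_tables[[nm]]$rr <- 1
      p$rr_tables[[nm]]$ci_low <- 1
      p$rr_tables[[nm]]$ci_high <- 1
    }
    p$epi$sp_responder <- p$settings$sp_target
    p$epi$sp_nonresponder_predialysis <- p$settings$sp_target
    p$epi$sp_nonresponder_dialysis <- p$settings$sp_target
    p
  })
}

strategy_life_years <- function(params, strategy = "cb") {
  run <- run_strategy(params, strategy)
  s <- phoscea:::strategy_streams(run, params)
  discount_stream(s$alive, params$settings$discount_rate,
                  params$settings$discount_timing)
}
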