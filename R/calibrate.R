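#' Calibrate the dialysis baseline annual mortality
#'
#' The model's dialysis baseline annual mortality is not a published
#' input: it is the one free parameter of the model, fixed by
#' one-dimensional calibration so that the continued-CB strategy's
#' discounted life expectancy per patient matches a known target
#' (6.868 years in the base case). All other parameters stay at their
#' configured values during calibration.
#'
#' @param params A `phoscea_parameters` object (the value of
#'   `epi$mortality_dialysis_annual` it carries is ignored).
#' @param target_life_years Target discounted life years per patient in
#'   the continued-CB arm.
#' @param interval Search interval for the annual probability.
#' @param tol Convergence tolerance passed to [stats::uniroot()].
#' @return A list with `mortality_dialysis_annual` (the calibrated
#'   probability), `achieved_life_years`, and `target_life_years`.
#' @export
#' @examples
#' \donttest{
#' calibrate_dialysis_mortality(default_parameters())$mortality_dialysis_annual
#' }
calibrate_dialysis_mortality <- function(params = default_parameters(),
                                         target_life_years = 6.868,
                                         interval = c(0.005, 0.95),
                                         tol = 1e-8) {
  cb_ly <- function(m) {
    p <- unclass(params)
    p$epi$mortality_dialysis_annual <- m
    p <- validate_parameters(p)
    run <- run_strategy(p, "cb")
    s <- strategy_streams(run, p)
    discount_stream(s$alive, p$settings$discount_rate, p$settings$discount_timing)
  }
  lo <- cb_ly(interval[2]); hi <- cb_ly(interval[1])
  if (target_life_years < lo || target_life_years > hi) {
    stopf("target %.3f life years outside attainable range [%.3f, %.3f]",
          target_life_years, lo, hi)
  }
  root <- stats::uniroot(function(m) cb_ly(m) - target_life_years,
                         interval = interval, tol = tol)
  list(mortality_dialysis_annual = root$root,
       achieved_life_years = cb_ly(root$root),
       target_life_years = target_life_years)
}
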