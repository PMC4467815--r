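test_that("rebate arithmetic matches the mandatory deduction and inverts cleanly", {
  expect_equal(apply_rebate(100, 0.075), 92.5)
  # Table 2's EUR 167.86 pack price is the ex-factory price net of 7.5%
  expect_equal(apply_rebate(167.86 / 0.925, 0.075), 167.86, tolerance = 1e-9)
  expect_equal(apply_rebate(55, 0), 55)
  expect_error(apply_rebate(-1, 0.1), "must be >= 0")
  for (f in c(0, 0.075, 0.3)) {
    expect_equal(apply_rebate(123.45 / (1 - f), f), 123.45, tolerance = 1e-9)
  }
})

test_that("cost per gram follows pack arithmetic, with the documented CA override", {
  expect_equal(cost_per_gram(167.86, 90, 750), 167.86 / 67.5)
  expect_equal(cost_per_gram(1, 1, 1000), 1)
  expect_error(cost_per_gram(10, 0, 750), "> 0")
  p <- base_params()
  expect_equal(drug_cost_per_gram(p, "lc"), 167.86 / 67.5)
  expect_equal(drug_cost_per_gram(p, "cc"), 2.09 / 75)
  # calcium acetate pack arithmetic (0.095/g) disagrees with the printed
  # 0.124/g; the configured override carries the printed value
  expect_equal(cost_per_gram(7.13, 60, 1250), 0.0951, tolerance = 1e-3)
  expect_equal(drug_cost_per_gram(p, "ca"), 0.124)
})

test_that("annual drug costs reproduce the published cost table within EUR 1", {
  p <- base_params()
  expect_equal(drug_annual_cost(p, "lc", "predialysis"), 1702, tolerance = 1 / 1702)
  expect_equal(drug_annual_cost(p, "lc", "dialysis"), 2042, tolerance = 1 / 2042)
  expect_equal(drug_annual_cost(p, "cc", "predialysis"), 30, tolerance = 1 / 30)
  expect_equal(drug_annual_cost(p, "cc", "dialysis"), 50, tolerance = 1 / 50)
  expect_equal(drug_annual_cost(p, "ca", "predialysis"), 68, tolerance = 1 / 68)
  expect_equal(drug_annual_cost(p, "ca", "dialysis"), 136, tolerance = 1 / 136)
  expect_equal(annual_drug_cost(0, 99, 365), 0)
})

test_that("comparator cost honours the composition switch", {
  p <- base_params()
  expect_equal(round(cb_annual_cost(p, "predialysis")), 49)
  expect_equal(round(cb_annual_cost(p, "dialysis")), 93)
  expect_equal(cb_annual_cost(p, "predialysis"),
               (drug_annual_cost(p, "cc", "predialysis") +
                drug_annual_cost(p, "ca", "predialysis")) / 2)
  p_cc <- tweak_params(p, function(x) { x$cb_composition <- "cc_only"; x })
  expect_equal(cb_annual_cost(p_cc, "dialysis"), 50, tolerance = 1 / 50)
  p_ca <- tweak_params(p, function(x) { x$cb_composition <- "ca_only"; x })
  expect_equal(round(cb_annual_cost(p_ca, "dialysis")), 136)
})

test_that("RR lookup is lower-inclusive and a non-decreasing step function", {
  p <- base_params()
  expect_equal(rr_for_sp(p$rr_tables$predialysis, 4.7), 1.83)
  expect_equal(rr_for_sp(p$rr_tables$dialysis, 8.5), 1.67)
  expect_equal(rr_for_sp(p$rr_tables$predialysis, 2.7), 1.00)
  # boundary SP belongs to the stratum whose lower bound equals it
  expect_equal(rr_for_sp(p$rr_tables$predialysis, 4.5), 1.83)
  expect_equal(rr_for_sp(p$rr_tables$dialysis, 9.0), 2.02)
  expect_error(rr_for_sp(p$rr_tables$dialysis, 0), "> 0")
  grid <- seq(0.1, 12, by = 0.05)
  for (nm in names(p$rr_tables)) {
    vals <- vapply(grid, function(s) rr_for_sp(p$rr_tables[[nm]], s), 0)
    expect_true(all(diff(vals) >= 0), info = nm)
  }
})

test_that("validation names the offending field and bound", {
  p <- base_params()
  expect_error(
    tweak_params(p, function(x) { x$utilities$utility_predialysis <- 1.2; x }),
    "utility_predialysis.*\\[0, 1\\]")
  expect_error(
    tweak_params(p, function(x) { x$epi$mortality_dialysis_annual <- NA_real_; x }),
    "mortality_dialysis_annual")
  expect_error(
    tweak_params(p, function(x) { x$settings$future_dialysis_cost_mode <- "bogus"; x }),
    "future_dialysis_cost_mode")
  expect_error(
    tweak_params(p, function(x) { x$efficacy$response_rate_lc_dialysis <- -0.1; x }),
    "response_rate_lc_dialysis")
  expect_error(
    tweak_params(p, function(x) { x$rr_tables$dialysis$sp_high[3] <- 2.9; x }),
    "tile|overlap|sp_low")
})

test_that("parameters survive a YAML round trip and the bundled config is the base case", {
  p <- base_params()
  f <- tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  bundled <- system.file("extdata", "params_basecase.yaml", package = "phoscea")
  expect_true(nzchar(bundled))
  expect_equal(unclass(load_parameters(bundled)), unclass(p), tolerance = 1e-12)
  expect_error(load_parameters(tempfile()), "not found")
})
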