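test_that("the scenario catalogue runs end to end and rejects unknown ids", {
  tab <- run_scenarios(base = base_params())
  expect_equal(nrow(tab), 10)
  expect_equal(tab$id, paste0("S", 1:10))
  expect_true(all(tab$dominance[tab$id != "S3"] == "dominant"))
  expect_error(run_scenario("S99", base_params()), "S99")
})

test_that("scenario directions match the one-way analysis", {
  p <- base_params()
  base <- run_ce(p)
  # S3: including unrelated future dialysis costs flips LC to cost-increasing
  s3 <- run_scenario("S3", p)
  expect_lt(base$incremental$delta_cost, 0)
  expect_gt(s3$incremental$delta_cost, 0)
  expect_true(is.numeric(s3$incremental$icer_per_qaly))
  # S5/S6: heavier discounting lowers QALYs, none raises them
  s5 <- run_scenario("S5", p)
  s6 <- run_scenario("S6", p)
  expect_lt(s5$cb$qalys, base$cb$qalys)
  expect_lt(s5$lc$qalys, base$lc$qalys)
  expect_gt(s6$cb$qalys, base$cb$qalys)
  expect_gt(s6$lc$qalys, base$lc$qalys)
  # S10: dropping the vomiting decrement benefits only the LC strategy
  s10 <- run_scenario("S10", p)
  expect_equal(s10$cb$qalys, base$cb$qalys, tolerance = 1e-12)
  expect_gt(s10$incremental$delta_qalys, base$incremental$delta_qalys)
  # S1/S2: shorter horizons shrink life years
  expect_lt(run_scenario("S1", p)$cb$life_years,
            run_scenario("S2", p)$cb$life_years)
  expect_lt(run_scenario("S2", p)$cb$life_years, base$cb$life_years)
  # S9: the alternate dialysis RR set weakens the mortality gradient
  s9 <- run_scenario("S9", p)
  expect_lt(s9$incremental$delta_qalys, base$incremental$delta_qalys)
})

test_that("PSA sampling has the stated marginal distributions", {
  p <- base_params()
  spec <- psa_spec(n_iterations = 1)
  set.seed(99)
  n <- 800
  resp <- rr45 <- u_pre <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_parameters(p, spec)
    resp[i] <- s$efficacy$response_rate_cb_predialysis
    rr45[i] <- s$rr_tables$predialysis$rr[6] # the 4.5-5.0 mg/dL stratum
    u_pre[i] <- s$utilities$utility_predialysis
  }
  # binomial at the trial size: mean = rate, support multiples of 1/28
  expect_equal(mean(resp), 0.445, tolerance = 0.015)
  expect_true(all(abs(resp * 28 - round(resp * 28)) < 1e-9))
  # normal from the printed CI: sd ~ (2.51 - 1.33) / 3.92
  expect_equal(sd(rr45), (2.51 - 1.33) / 3.92, tolerance = 0.15)
  # beta: inside the unit interval, centred at the base utility
  expect_true(all(u_pre > 0 & u_pre < 1))
  expect_equal(mean(u_pre), 0.71, tolerance = 0.02)
})

test_that("PSA is reproducible bit for bit under a fixed seed", {
  p <- base_params()
  a <- run_psa(p, psa_spec(n_iterations = 25), seed = 11)
  b <- run_psa(p, psa_spec(n_iterations = 25), seed = 11)
  expect_identical(a$points, b$points)
  expect_identical(a$ceac, b$ceac)
  expect_identical(a$fraction_dominant, b$fraction_dominant)
  c2 <- run_psa(p, psa_spec(n_iterations = 25), seed = 12)
  expect_false(identical(a$points, c2$points))
})

test_that("dominance implies cost-effectiveness at every threshold", {
  psa <- run_psa(base_params(), psa_spec(n_iterations = 40), seed = 2)
  expect_true(all(psa$fraction_dominant <= psa$ceac$fraction_cost_effective))
})

test_that("the PSA cloud collapses onto the deterministic result as variances vanish", {
  p0 <- tweak_params(base_params(), function(x) {
    x$efficacy$n_trial_cb_pre <- 1e7
    x$efficacy$n_trial_lc_pre <- 1e7
    x$efficacy$n_trial_cb_dial <- 1e7
    x$efficacy$n_trial_lc_dial <- 1e7
    for (nm in names(x$rr_tables)) {
      x$rr_tables[[nm]]$ci_low <- x$rr_tables[[nm]]$rr
      x$rr_tables[[nm]]$ci_high <- x$rr_tables[[nm]]$rr
    }
    x$epi$ci_rr_progression <- rep(x$epi$rr_progression_per_mgdl, 2)
    x
  })
  det <- run_ce(p0)
  psa <- run_psa(p0, psa_spec(n_iterations = 5, cost_cv = 0, utility_cv = 0,
                              mortality_dialysis_cv = 0), seed = 4)
  expect_equal(psa$points$delta_cost,
               rep(det$incremental$delta_cost, 5), tolerance = 0.01)
  expect_equal(psa$points$delta_qalys,
               rep(det$incremental$delta_qalys, 5), tolerance = 0.01)
})
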