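test_that("relative-risk adjustment works in both domains", {
  expect_equal(mortality_probability(0.123, 1.0), 0.123)
  expect_equal(mortality_probability(0.123, 1.90), 0.220710, tolerance = 1e-5)
  expect_equal(mortality_probability(0.123, 1.90, "multiplicative"), 0.2337,
               tolerance = 1e-4)
  expect_equal(mortality_probability(0.6, 5, "multiplicative"), 1) # capped
  expect_lt(mortality_probability(0.6, 5, "rate"), 1)
  expect_equal(mortality_probability(0, 3), 0)
})

test_that("progression accelerates only above the SP target", {
  expect_equal(progression_probability(0.143, 4.6, 4.6, 1.19), 0.143)
  expect_equal(progression_probability(0.143, 4.0, 4.6, 1.19), 0.143)
  expect_equal(progression_probability(0.143, 5.7, 4.6, 1.19),
               1 - (1 - 0.143)^(1.19^1.1))
  expect_equal(progression_probability(0.143, 5.7, 4.6, 1.19), 0.170440,
               tolerance = 1e-5)
  expect_equal(progression_probability(0, 9, 4.6, 1.19), 0)
})

test_that("with flat risks the engine transitions equal the base rates", {
  p <- flat_risk_params()
  for (arm in build_arms(p, "lc")) {
    tr <- build_transitions(arm, p)
    expect_identical(tr$p_die_pre, p$epi$mortality_predialysis_annual)
    expect_identical(tr$p_prog, p$epi$progression_annual)
    expect_true(all(tr$p_die_dial == p$epi$mortality_dialysis_annual))
  }
})

test_that("one cycle of the cohort matches the hand-computed death-first split", {
  p <- flat_risk_params()
  trace <- run_cohort(build_arms(p, "cb")[[1]], p)
  agg <- phoscea:::aggregate_states(trace$occupancy, trace$arm$dialysis_mix)
  expect_equal(unname(agg[1, ]), c(1, 0, 0))
  expect_equal(unname(agg[2, ]),
               c(0.877 * 0.857, 0.877 * 0.143, 0.123), tolerance = 1e-9)
})

test_that("occupancy is conserved and death absorbing over 40 cycles", {
  fixtures <- c(list(base_params()),
                lapply(1:3, function(s) random_fixture(s)$params))
  for (p in fixtures) {
    for (strategy in c("cb", "lc")) {
      run <- run_strategy(p, strategy)
      for (tr in run$traces) {
        expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
        expect_true(all(diff(tr$occupancy[, ncol(tr$occupancy)]) >= -1e-12))
      }
      expect_true(all(abs(rowSums(run$trace) - 1) < 1e-9))
      expect_true(all(diff(run$trace[, "dead"]) >= -1e-12))
    }
  }
})

test_that("certain dialysis death empties the dialysis state each cycle", {
  p <- tweak_params(flat_risk_params(), function(x) {
    x$epi$mortality_dialysis_annual <- 1
    x
  })
  trace <- run_cohort(build_arms(p, "cb")[[1]], p)
  K <- nrow(trace$arm$dialysis_mix)
  for (t in seq_len(trace$cycles)) {
    # end-of-cycle dialysis occupancy is this cycle's arrivals only
    expect_equal(unname(trace$occupancy[t + 1, 1 + seq_len(K)]),
                 unname(trace$inflow[t, ]), tolerance = 1e-12)
  }
})

test_that("half-cycle correction averages adjacent cycles", {
  m <- rbind(c(1, 0, 0), c(0.8, 0.1, 0.1))
  expect_equal(unname(half_cycle_correct(m)), cbind(0.9, 0.05, 0.05))
  const <- matrix(0.5, nrow = 5, ncol = 2)
  expect_equal(half_cycle_correct(const), const[-1, ])
  expect_error(half_cycle_correct(matrix(1, 1, 3)), "at least 2")
  # linear decline: corrected sums equal the trapezoid rule
  k <- 10
  s <- matrix(seq(1, 0, length.out = k + 1), ncol = 1)
  expect_equal(sum(half_cycle_correct(s)),
               sum(s) - (s[1] + s[k + 1]) / 2, tolerance = 1e-12)
})

test_that("life years match the geometric closed form to 1e-9", {
  for (pd in c(0.05, 0.123, 0.5)) {
    for (r in c(0, 0.03)) {
      p <- tweak_params(flat_risk_params(), function(x) {
        x$epi$mortality_predialysis_annual <- pd
        x$epi$progression_annual <- 0
        x$epi$ci_progression <- c(0, 0)
        x$settings$discount_rate <- r
        x
      })
      H <- p$settings$horizon_years
      expect_equal(strategy_life_years(p, "cb"),
                   geometric_survival_ly(pd, H, r), tolerance = 1e-9)
    }
  }
})

test_that("raising mortality or progression moves outcomes the right way", {
  p <- base_params()
  ly0 <- strategy_life_years(p, "cb")
  p_hi_mort <- tweak_params(p, function(x) {
    x$rr_tables$predialysis$rr <- x$rr_tables$predialysis$rr * 1.3
    x$rr_tables$predialysis$ci_high <- pmax(
      x$rr_tables$predialysis$ci_high, x$rr_tables$predialysis$rr)
    x
  })
  expect_lt(strategy_life_years(p_hi_mort, "cb"), ly0)
  dfy <- function(pp) {
    run <- run_strategy(pp, "cb")
    s <- phoscea:::strategy_streams(run, pp)
    discount_stream(s$predialysis, pp$settings$discount_rate)
  }
  p_hi_prog <- tweak_params(p, function(x) {
    x$epi$progression_annual <- 0.25
    x$epi$ci_progression <- c(0.136, 0.30)
    x
  })
  expect_lt(dfy(p_hi_prog), dfy(p))
})
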