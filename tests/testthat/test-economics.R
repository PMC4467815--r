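test_that("discounting follows the half-cycle timing convention", {
  expect_equal(discount_stream(100, 0), 100)
  expect_equal(discount_stream(c(100, 100), 0.03),
               100 / 1.03^0.5 + 100 / 1.03^1.5)
  expect_equal(discount_stream(c(100, 100), 0.03, "end_cycle"),
               100 / 1.03 + 100 / 1.03^2)
  expect_equal(discount_stream(numeric(0), 0.05), 0)
})

test_that("discounted value never exceeds undiscounted for nonnegative streams", {
  set.seed(42)
  for (i in 1:20) {
    v <- runif(15, 0, 100)
    r <- runif(1, 0.001, 0.1)
    expect_lt(discount_stream(v, r), sum(v))
    expect_equal(discount_stream(v, 0), sum(v))
  }
})

test_that("utility accrual matches the state utilities and vomiting decrement", {
  p <- base_params()
  arms <- build_arms(p, "lc")
  lc_resp <- arms[[2]]
  K <- nrow(lc_resp$dialysis_mix)
  make_trace <- function(col_value_index) {
    occ <- matrix(0, 3, K + 2)
    occ[, col_value_index] <- 1
    list(occupancy = occ, corrected = phoscea:::half_cycle_matrix(occ),
         inflow = matrix(0, 2, K), arm = lc_resp, cycles = 2)
  }
  # one patient-year in predialysis on LC
  tr_pre <- make_trace(1)
  expect_equal(arm_qaly_stream(tr_pre, p),
               rep(0.71 - 0.040 * 0.04082, 2), tolerance = 1e-12)
  expect_equal(arm_drug_cost_stream(tr_pre, p),
               rep(drug_annual_cost(p, "lc", "predialysis"), 2))
  # one patient-year in dialysis on LC: 0.61 - 0.072 x 0.04082
  k_lc <- 1 + which(lc_resp$dialysis_mix$drug == "lc")
  tr_dial <- make_trace(k_lc)
  expect_equal(arm_qaly_stream(tr_dial, p), rep(0.60706, 2), tolerance = 1e-4)
  # zero occupancy accrues nothing
  tr_dead <- make_trace(K + 2)
  expect_equal(arm_qaly_stream(tr_dead, p), c(0, 0))
  expect_equal(arm_drug_cost_stream(tr_dead, p), c(0, 0))
})

test_that("incremental comparison reproduces the headline NMB and ICER arithmetic", {
  mk <- function(cost, qalys, ly) list(total_cost = cost, qalys = qalys, life_years = ly)
  # cost-saving, QALY-gaining: dominant, NMB = lambda dQ - dC
  inc <- incremental(mk(5044e3, 4579, 6868), mk(5044e3 - 3875e3, 4579 + 73.88, 6981),
                     lambda = 30000)
  expect_equal(inc$dominance, "dominant")
  expect_equal(inc$icer_per_qaly, "dominant")
  expect_equal(inc$nmb, 30000 * 73.88 + 3875e3) # ~ EUR 6,092 thousand
  expect_equal(inc$nmb / 1000, 6091.4, tolerance = 1e-4)
  # cost-increasing variant: ICER = dC / dQ
  inc2 <- incremental(mk(0, 0, 0), mk(3336e3, 73.88, 113), lambda = 30000)
  expect_equal(inc2$dominance, "tradeoff_NE")
  expect_equal(inc2$icer_per_qaly, 3336e3 / 73.88)
  expect_equal(inc2$icer_per_qaly, 45155, tolerance = 1e-4)
  # no difference at all
  inc3 <- incremental(mk(10, 5, 5), mk(10, 5, 5), lambda = 30000)
  expect_equal(inc3$icer_per_qaly, "no_difference")
})

test_that("dominance classification matches the sign quadrant for random deltas", {
  set.seed(7)
  mk <- function(cost, qalys) list(total_cost = cost, qalys = qalys, life_years = qalys)
  for (i in 1:200) {
    dC <- runif(1, -1e6, 1e6)
    dQ <- runif(1, -100, 100)
    inc <- incremental(mk(0, 0), mk(dC, dQ), lambda = 30000)
    want <- if (dC < 0 && dQ > 0) "dominant"
            else if (dC > 0 && dQ < 0) "dominated"
            else if (dC >= 0 && dQ >= 0) "tradeoff_NE" else "tradeoff_SW"
    expect_identical(inc$dominance, want)
    if (want %in% c("dominant", "dominated")) {
      expect_identical(inc$icer_per_qaly, want)
    } else {
      expect_equal(inc$icer_per_qaly, dC / dQ)
    }
  }
})

test_that("net monetary benefit is linear in lambda and anchored at -delta cost", {
  mk <- function(cost, qalys) list(total_cost = cost, qalys = qalys, life_years = qalys)
  dC <- -3.5e6; dQ <- 180
  n0 <- incremental(mk(0, 0), mk(dC, dQ), 0)$nmb
  n1 <- incremental(mk(0, 0), mk(dC, dQ), 10000)$nmb
  n2 <- incremental(mk(0, 0), mk(dC, dQ), 20000)$nmb
  expect_equal(n0, -dC)
  expect_equal(n2 - n1, n1 - n0)
})

test_that("attributable dialysis costing charges only avoided dialysis time", {
  p <- base_params()
  dial <- c(0.1, 0.2, 0.3)
  pre <- c(0.5, 0.4, 0.3)
  same <- dialysis_cost_streams(dial, dial, p, pre_cb = pre, pre_lc = pre)
  expect_equal(same$cb, c(0, 0, 0))
  expect_equal(same$lc, c(0, 0, 0))
  # LC keeps more patients dialysis-free: CB pays for the difference
  pre_lc <- pre + c(0.05, 0.1, 0.1)
  d <- dialysis_cost_streams(dial, dial, p, pre_cb = pre, pre_lc = pre_lc)
  expect_equal(d$cb, c(0.05, 0.1, 0.1) * p$settings$dialysis_annual_cost)
  expect_equal(d$lc, c(0, 0, 0))
  p_full <- tweak_params(p, function(x) {
    x$settings$future_dialysis_cost_mode <- "full"; x
  })
  full <- dialysis_cost_streams(dial, dial * 2, p_full)
  expect_equal(full$cb, dial * p$settings$dialysis_annual_cost)
  expect_equal(full$lc, 2 * dial * p$settings$dialysis_annual_cost)
  expect_error(dialysis_cost_streams(dial, dial[-1], p), "horizon")
})

test_that("raising the discount rate lowers QALYs in both strategies", {
  ce3 <- run_ce(base_params())
  p6 <- tweak_params(base_params(), function(x) { x$settings$discount_rate <- 0.06; x })
  ce6 <- run_ce(p6)
  expect_lt(ce6$cb$qalys, ce3$cb$qalys)
  expect_lt(ce6$lc$qalys, ce3$lc$qalys)
})
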