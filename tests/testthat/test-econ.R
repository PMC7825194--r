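test_that("the start occupancy maps responders to the controlled band", {
  expect_equal(unname(build_cohort_start(1)), c(1, 0, 0, 0))
  expect_equal(unname(build_cohort_start(0)), c(0, 0.5, 0.5, 0))
  expect_equal(unname(build_cohort_start(0.36)), c(0.36, 0.32, 0.32, 0))
  expect_equal(unname(build_cohort_start(0.4, split = c(0.25, 0.75))),
               c(0.4, 0.15, 0.45, 0))
  expect_error(build_cohort_start(0.5, split = c(0.6, 0.6)), "summing to 1")
})

test_that("occupancy is conserved at every cycle over the full horizon", {
  spec <- markov_spec()
  out <- run_markov(spec, build_cohort_start(0.5))
  expect_equal(nrow(out$trace), 201)  # 50 years of 3-month cycles
  expect_true(all(abs(rowSums(out$trace) - 1) < 1e-12))
  expect_true(all(out$trace >= -1e-15))
  expect_gt(out$Q, 0)
  expect_gt(out$t2, 0)
  expect_lte(out$t2, spec$horizon_years)
})

test_that("degenerate cohorts and payoff streams match closed forms", {
  spec <- markov_spec()
  dead <- c(lt6 = 0, b6_8 = 0, gt8 = 0, dead = 1)
  out <- run_markov(spec, dead)
  expect_equal(out$Q, 0)
  expect_equal(out$C_nondrug, 0)
  expect_equal(out$t2, 0)

  # no discounting, mortality, dropout or flares: Q = u * horizon exactly
  flat <- markov_spec(discount_annual = 0, mortality_annual = 0,
                      dropout_scale_days = Inf,
                      flare_rate_annual = c(0, 0, 0),
                      utility = c(0.8, 0.8, 0.8),
                      care_cost_annual = c(0, 0, 0))
  out2 <- run_markov(flat, build_cohort_start(0.3))
  expect_equal(out2$Q, 0.8 * 50, tolerance = 1e-12)
  expect_equal(out2$t2, 50, tolerance = 1e-12)

  # constant cost stream matches the discrete discounted annuity
  ann <- markov_spec(discount_annual = 0.035, mortality_annual = 0,
                     dropout_scale_days = Inf,
                     flare_rate_annual = c(0, 0, 0),
                     care_cost_annual = c(1200, 1200, 1200))
  out3 <- run_markov(ann, build_cohort_start(0.7))
  closed <- discounted_annuity(1200, 0.25, 0.035, 200)
  expect_lt(abs(out3$C_nondrug - closed) / closed, 1e-10)
})

test_that("single-cycle transition rows sum to one and hazards fall over time", {
  spec <- markov_spec()
  p_dc <- numeric(0)
  for (i in c(0, 1, 10, 100, 199)) {
    Tm <- ctsroi:::cycle_transition_matrix(spec, i)
    expect_true(all(abs(rowSums(Tm) - 1) < 1e-12))
    p_dc <- c(p_dc, 1 - Tm[1, 1] / (1 - (1 - (1 - spec$mortality_annual)^0.25)))
  }
  expect_true(all(diff(p_dc) < 0))  # shape < 1: discontinuation risk declines
})

test_that("net monetary benefit is the printed linear form", {
  expect_equal(nmb(Q1 = 1, C1 = 10000, Q2 = 1.5, C2 = 15000, lambda = 20000),
               5000)
  expect_equal(nmb(2, 300, 2, 300, 25000), 0)
  expect_lt(nmb(1, 0, 1.1, 20000 * 0.1 + 1, 20000), 0)
  expect_gt(nmb(1, 0, 1.1, 20000 * 0.1 - 1, 20000), 0)
})

test_that("expected persistence matches its closed forms", {
  # no dropout, no discounting: the full horizon
  expect_equal(expected_persistence(0.5, Inf, 20, 0), 20)

  # exponential dropout at rate h per year: exact method converges to 1/h
  h <- 0.4
  dpy <- 365.25
  t2 <- expected_persistence(1, dpy / h, horizon_years = 20 / h,
                             discount_annual = 0, method = "exact")
  expect_lt(abs(t2 - 1 / h) / (1 / h), 1e-6)

  # higher hazard level, shorter persistence
  t_short <- expected_persistence(0.5, 1000, 50, 0.035)
  t_long <- expected_persistence(0.5, 10000, 50, 0.035)
  expect_lt(t_short, t_long)

  # the cycle method reproduces the Markov trace's on-treatment years
  spec <- markov_spec(mortality_annual = 0)
  out <- run_markov(spec, build_cohort_start(0.5))
  t_cycle <- expected_persistence(spec$dropout_shape, spec$dropout_scale_days,
                                  spec$horizon_years, spec$discount_annual,
                                  spec$cycle_years, method = "cycle",
                                  days_per_year = spec$days_per_year)
  expect_equal(out$t2, t_cycle, tolerance = 1e-12)
})

test_that("the maximum reimbursement price zeroes the net monetary benefit", {
  expect_equal(max_reimbursement_price(C1 = 10000, C2_nondrug = 8000,
                                       Q1 = 1, Q2 = 1.2, lambda = 20000,
                                       t2 = 4),
               1500)
  expect_equal(max_reimbursement_price(100, 100, 2, 2, 20000, 5), 0)
  set.seed(80)
  for (i in 1:100) {
    Q1 <- runif(1, 5, 15); Q2 <- Q1 + runif(1, -1, 1)
    C1 <- runif(1, 1e3, 5e4); C2n <- runif(1, 1e3, 5e4)
    lambda <- runif(1, 2e4, 3e4); t2 <- runif(1, 0.5, 20)
    P2 <- max_reimbursement_price(C1, C2n, Q1, Q2, lambda, t2)
    expect_lt(abs(nmb(Q1, C1, Q2, C2n + P2 * t2, lambda)), 1e-8)
  }
  expect_error(max_reimbursement_price(1, 1, 1, 1, 20000, 0), "positive")

  # dominance: better QALYs and lower non-drug costs leave pricing headroom
  expect_gt(max_reimbursement_price(12000, 9000, 8, 8.4, 20000, 6), 0)
  # price increases with incremental benefit
  p_lo <- max_reimbursement_price(1e4, 9e3, 8, 8.1, 2e4, 6)
  p_hi <- max_reimbursement_price(1e4, 9e3, 8, 8.5, 2e4, 6)
  expect_gt(p_hi, p_lo)
})
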