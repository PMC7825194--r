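table3_priors <- function() {
  # comparator (allopurinol) and new-treatment (febuxostat) priors of a
  # representative base-case design
  list(p1 = beta_dist(7.1, 12.4), p2 = beta_dist(36.4, 17.6))
}

test_that("market size follows the incidence model and the halving rule", {
  m <- market_model(annual_incidence = 20000, horizon_years = 10, uptake = 1)
  expect_equal(market_size(m, 6), 200000)
  expect_equal(market_size(m, 8), 100000)
  m0 <- market_model(annual_incidence = 20000, horizon_years = 0, uptake = 1)
  expect_equal(market_size(m0, 6), 0)
  half <- market_model(annual_incidence = 20000, horizon_years = 10,
                       uptake = 0.5)
  expect_equal(market_size(half, 6), 100000)
})

test_that("trial cost is fixed plus per-subject", {
  inp <- roi_inputs()
  expect_equal(trial_cost(0, inp), 5e6)
  expect_equal(trial_cost(600, inp), 17e6)
  expect_lt(trial_cost(100, inp), trial_cost(101, inp))
})

test_that("the ROI payoff has a hard termination branch at the minimum price", {
  inp <- roi_inputs()  # P_min = 70, C_PM = 10
  expect_equal(roi_single(69.99, t2 = 5, S = 1e6, Ctrial = 17e6, inp), 0)
  expect_equal(roi_single(100, t2 = 5, S = 1e6, Ctrial = 17e6, inp),
               433e6)
  # the boundary launches
  expect_equal(roi_single(70, t2 = 5, S = 1e6, Ctrial = 17e6, inp),
               (70 - 10) * 5 * 1e6 - 17e6)
  # vectorized
  expect_equal(roi_single(c(0, 70, 200), 2, 10, 5, inp),
               c(0, (70 - 10) * 2 * 10 - 5, (200 - 10) * 2 * 10 - 5))
})

test_that("expected ROI is reproducible and its grid is validated", {
  pr <- table3_priors()
  econ <- markov_spec()
  grid <- c(50, 100, 150, 200, 300, 400, 500, 600)
  r1 <- expected_roi(pr$p1, pr$p2, grid, R = 500, seed = 90, econ = econ,
                     roi = roi_inputs(), market = market_model(),
                     inclusion_threshold = 6)
  r2 <- expected_roi(pr$p1, pr$p2, grid, R = 500, seed = 90, econ = econ,
                     roi = roi_inputs(), market = market_model(),
                     inclusion_threshold = 6)
  expect_identical(r1, r2)
  expect_equal(r1$n, grid)
  expect_equal(sum(r1$optimal), 1L)
  expect_true(all(is.finite(r1$expected_roi)))
  expect_true(all(r1$p_termination >= 0 & r1$p_termination <= 1))
  expect_error(expected_roi(pr$p1, pr$p2, c(100, 50), 10, 1, econ,
                            roi_inputs(), market_model(), 6),
               "strictly increasing")
})

test_that("when every replicate price is below the minimum, ROI is exactly zero", {
  pr <- table3_priors()
  high_min <- roi_inputs(minimum_price = 1e9)
  r <- expected_roi(pr$p1, pr$p2, c(50, 100, 200), R = 300, seed = 91,
                    econ = markov_spec(), roi = high_min,
                    market = market_model(), inclusion_threshold = 6)
  expect_identical(r$expected_roi, c(0, 0, 0))
  expect_identical(r$p_termination, c(1, 1, 1))
  expect_true(r$optimal[1])  # ties break towards the smallest n
})

test_that("increasing the per-subject cost lowers expected ROI by exactly 2 n delta", {
  # well-separated priors and P_min = 0 keep every replicate in the revenue
  # branch, which the exact-2-n-delta relation requires
  pr <- list(p1 = beta_dist(100, 900), p2 = beta_dist(900, 100))
  econ <- markov_spec()
  mk <- market_model()
  base_in <- roi_inputs(minimum_price = 0)
  bump_in <- roi_inputs(minimum_price = 0, trial_variable_cost = 2e4 + 500)
  grid <- c(50, 200, 600)
  a <- expected_roi(pr$p1, pr$p2, grid, R = 200, seed = 92, econ = econ,
                    roi = base_in, market = mk, inclusion_threshold = 6)
  b <- expected_roi(pr$p1, pr$p2, grid, R = 200, seed = 92, econ = econ,
                    roi = bump_in, market = mk, inclusion_threshold = 6)
  expect_equal(a$expected_roi - b$expected_roi, 2 * grid * 500,
               tolerance = 1e-9)
})

test_that("degenerate priors remove the value of sampling", {
  # near-point-mass priors: the posterior barely moves whatever the data
  p1 <- beta_dist(0.30 * 1e8, 0.70 * 1e8)
  p2 <- beta_dist(0.65 * 1e8, 0.35 * 1e8)
  no_cost <- roi_inputs(trial_fixed_cost = 0, trial_variable_cost = 0,
                        minimum_price = 0)
  r <- expected_roi(p1, p2, c(50, 100, 300, 600), R = 200, seed = 93,
                    econ = markov_spec(), roi = no_cost,
                    market = market_model(), inclusion_threshold = 6)
  spread <- diff(range(r$expected_roi)) / abs(mean(r$expected_roi))
  expect_lt(spread, 1e-6)
  expect_lt(abs(r$expected_roi[r$optimal] - r$expected_roi[1]),
            1e-9 * abs(r$expected_roi[1]))
})

test_that("with free trials, more data cannot hurt the expected payoff", {
  pr <- table3_priors()
  econ <- markov_spec()
  grid <- c(50, 100, 200, 400)
  R <- 4000L
  # convex payoff case: minimum price equal to the marginal cost
  inp <- roi_inputs(trial_fixed_cost = 0, trial_variable_cost = 0,
                    minimum_price = 10)
  ev <- evaluate_design(pr$p1, pr$p2, grid, R = R, seed = 94, econ = econ)
  S <- market_size(market_model(), 6)
  roi_mat <- sapply(grid, function(n) {
    d <- ev[ev$n == n, ]
    roi_single(d$P2, d$t2, S, 0, inp)
  })
  for (k in seq_len(length(grid) - 1)) {
    dif <- roi_mat[, k + 1] - roi_mat[, k]
    expect_gt(mean(dif), -3 * sd(dif) / sqrt(R))
  }
})

test_that("replicate-level evaluations carry coherent posterior quantities", {
  pr <- table3_priors()
  ev <- evaluate_design(pr$p1, pr$p2, c(100), R = 50, seed = 95,
                        econ = markov_spec())
  expect_equal(nrow(ev), 50)
  expect_true(all(ev$m1 >= 0 & ev$m1 <= 100))
  expect_true(all(ev$post1 > 0 & ev$post1 < 1))
  # posterior mean consistent with the conjugate update at the drawn data
  i <- 7
  post <- posterior_update(pr$p1, ev$m1[i], 100)
  expect_equal(ev$post1[i], posterior_point(post))
  # P2 is the zero-NMB price given the replicate's econ outcomes
  expect_equal(nmb(ev$Q1[i], ev$C1[i], ev$Q2[i],
                   ev$C2_nondrug[i] + ev$P2[i] * ev$t2[i], 20000),
               0, tolerance = 1e-8)
})
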