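test_that("cohort sampling is deterministic under a seed", {
  pop <- population_spec()
  adh <- adherence_params()
  iiv <- c(ka = 0.3, CL = 0.25)
  a <- sample_population(pop, 50, seed = 123, iiv = iiv, adherence = adh)
  b <- sample_population(pop, 50, seed = 123, iiv = iiv, adherence = adh)
  expect_identical(a, b)
  c_ <- sample_population(pop, 50, seed = 124, iiv = iiv, adherence = adh)
  expect_false(identical(a$covariates, c_$covariates))
})

test_that("zero-variance attribute distributions give identical subjects", {
  pop <- population_spec(baseline_sua = list(meanlog = log(9), sdlog = 0),
                         weight = list(mean = 80, sd = 0, min = 40, max = 160),
                         age = list(mean = 55, sd = 0, min = 20, max = 90))
  adh <- adherence_params(implementation_dispersion = 0)
  ch <- sample_population(pop, 20, seed = 1, adherence = adh)
  expect_equal(unique(ch$covariates$baseline_sua), 9)
  expect_equal(unique(ch$covariates$weight), 80)
  expect_equal(unique(ch$p_impl), 0.9)
})

test_that("implementation probabilities have the configured population mean", {
  adh <- adherence_params(implementation_mean = 0.9,
                          implementation_dispersion = 1)
  ch <- sample_population(population_spec(), 10000, seed = 2026,
                          adherence = adh)
  expect_lt(abs(mean(ch$p_impl) - 0.9), 0.01)
  expect_gt(sd(ch$p_impl), 0)  # genuinely subject-specific
})

test_that("inclusion is strict, order-preserving and idempotent", {
  df <- data.frame(baseline_sua = c(7.5, 8.0, 9.1, 5.9, 8.00001))
  kept6 <- apply_inclusion(df, 6)
  expect_equal(kept6$baseline_sua, c(7.5, 8.0, 9.1, 8.00001))
  kept8 <- apply_inclusion(df, 8)
  expect_equal(kept8$baseline_sua, c(9.1, 8.00001))  # 8.0 excluded (strict)
  expect_equal(apply_inclusion(kept8, 8), kept8)
  expect_equal(apply_inclusion(df, 0), df)
  expect_warning(apply_inclusion(df, 50), "all subjects")
})

test_that("dosing histories honour implementation probability and dropout", {
  adh_none <- adherence_params(implementation_dispersion = 0,
                               weibull_scale = Inf)
  h <- sample_dosing_history(adh_none, p_impl = 1, dose = 300,
                             duration = 100, seed = 3)
  expect_equal(h$taken, rep(1L, 100))
  expect_true(is.na(h$dropout_day))

  h0 <- sample_dosing_history(adh_none, p_impl = 0, dose = 300,
                              duration = 100, seed = 3)
  expect_equal(h0$taken, rep(0L, 100))

  adh <- adherence_params(weibull_shape = 0.5, weibull_scale = 300)
  hd <- sample_dosing_history(adh, p_impl = 1, dose = 300, duration = 400,
                              seed = 11)
  if (!is.na(hd$dropout_day)) {
    expect_true(all(hd$taken[hd$dropout_day:400] == 0L))
  }
})

test_that("the dropout-free fraction follows the Weibull survival curve", {
  shape <- 0.5
  scale <- 300
  adh <- adherence_params(weibull_shape = shape, weibull_scale = scale)
  n <- 10000L
  draws <- ctsroi:::sample_dosing_matrix(adh, rep(1, n), duration = 400L,
                                         seed = 77)
  d <- draws$dropout_day
  for (t in c(30L, 100L, 250L, 400L)) {
    s_hat <- mean(is.na(d) | d > t)
    s_true <- exp(-(t / scale)^shape)
    se <- sqrt(s_true * (1 - s_true) / n)
    expect_lt(abs(s_hat - s_true), 3 * se + 1e-12)
  }
})

test_that("simulated arms are reproducible and dropouts revert to baseline exactly", {
  design <- default_designs()[["psi1"]]
  pop <- population_spec()
  # discontinuation virtually certain and early
  adh <- adherence_params(weibull_shape = 0.5, weibull_scale = 0.001)
  cohort <- sample_population(pop, 25, seed = 4, iiv = c(CL = 0.2),
                              adherence = adh)
  cohort <- apply_inclusion(cohort, design$inclusion_threshold)
  pk <- test_pk1()
  pd <- test_pd(Imax = 0.9, IC50 = 2)
  res1 <- simulate_arm(design, 1, cohort, pk, pd, adh, seed = 5)
  res2 <- simulate_arm(design, 1, cohort, pk, pd, adh, seed = 5)
  expect_identical(res1, res2)
  expect_true(all(!is.na(res1$dropout_day)))
  expect_identical(res1$final_sua, res1$baseline_sua)
  # everyone entered above 6 mg/dL, so reversion means zero response
  expect_equal(response_rate(res1), 0)
})

test_that("response rate uses a strict 6 mg/dL cutoff", {
  res <- data.frame(final_sua = c(rep(4, 36), rep(7, 64)))
  res$responder <- res$final_sua < 6
  expect_equal(response_rate(res), 0.36)
  all_resp <- data.frame(final_sua = rep(5, 10))
  all_resp$responder <- TRUE
  expect_equal(response_rate(all_resp), 1)
  border <- data.frame(final_sua = c(6.0, 5.999999))
  border$responder <- border$final_sua < 6
  expect_equal(response_rate(border), 0.5)
  expect_error(response_rate(data.frame()), "non-empty")
})

test_that("mean response is non-decreasing in the implementation probability", {
  design <- default_designs()[["psi1"]]
  pop <- population_spec()
  pk <- test_pk1()
  pd <- test_pd(Imax = 0.9, IC50 = 1.7)
  rates <- vapply(c(0.5, 0.7, 0.9, 1.0), function(p) {
    adh <- adherence_params(implementation_mean = p,
                            implementation_dispersion = 0,
                            weibull_scale = Inf)
    cohort <- sample_population(pop, 80, seed = 6, adherence = adh)
    cohort <- apply_inclusion(cohort, design$inclusion_threshold)
    response_rate(simulate_arm(design, 1, cohort, pk, pd, adh, seed = 7))
  }, 0)
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[4], rates[1])  # effect visible end to end
})
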