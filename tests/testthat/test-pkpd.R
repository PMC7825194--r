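test_that("individualization is identity at reference covariates with zero effects", {
  pk <- test_pk1()
  pd <- test_pd()
  cm <- covariate_model()
  cov <- subject_covariates(8, cm$ref_weight, cm$ref_age)
  ind <- individualize_params(pk, pd, cov, cmod = cm)
  expect_equal(unclass(ind$pk), unclass(pk))
  expect_equal(unclass(ind$pd), unclass(pd))
})

test_that("covariates and random effects act multiplicatively", {
  pk <- test_pk1()
  pd <- test_pd()
  cm <- covariate_model()
  heavy <- subject_covariates(8, 2 * cm$ref_weight, cm$ref_age)
  ind <- individualize_params(pk, pd, heavy, cmod = cm)
  expect_equal(ind$pk$CL, pk$CL * 2^0.75)
  expect_equal(ind$pk$V1, pk$V1 * 2)
  expect_equal(ind$pd$CLr_ua, pd$CLr_ua * 2^0.75)
  expect_equal(ind$pd$V_ua, pd$V_ua * 2)

  ref <- subject_covariates(8, cm$ref_weight, cm$ref_age)
  ind2 <- individualize_params(pk, pd, ref, eta_pk = c(ka = log(2)), cmod = cm)
  expect_equal(ind2$pk$ka, 2 * pk$ka)

  old <- subject_covariates(8, cm$ref_weight, cm$ref_age + 10)
  ind3 <- individualize_params(pk, pd, old, cmod = cm)
  expect_equal(ind3$pd$CLr_ua, pd$CLr_ua * exp(cm$age_slope_renal * 10))
  expect_equal(ind3$pk$CL, pk$CL)  # age acts on renal clearances only

  expect_error(subject_covariates(-1, 70, 60), "baseline_sua")
})

test_that("concentration profile matches a numerical ODE solution", {
  times <- seq(0, 6, by = 0.05)
  for (pk in list(test_pk1(), test_pk2())) {
    hist <- dosing_history(100, 6, taken = c(1, 0, 0, 0, 0, 0))
    closed <- concentration_profile(pk, hist, times)
    oracle <- ode_concentration(pk, 100, times)
    expect_lt(max(abs(closed - oracle)) / max(oracle), 1e-3)
  }
})

test_that("concentration obeys superposition and skipped doses contribute nothing", {
  pk <- test_pk1()
  times <- seq(0, 5, by = 0.1)
  none <- dosing_history(100, 5, taken = rep(0, 5))
  expect_equal(concentration_profile(pk, none, times), rep(0, length(times)))

  two <- dosing_history(100, 5, taken = c(1, 0, 1, 0, 0))
  d0 <- dosing_history(100, 5, taken = c(1, 0, 0, 0, 0))
  d2 <- dosing_history(100, 5, taken = c(0, 0, 1, 0, 0))
  expect_equal(concentration_profile(pk, two, times),
               concentration_profile(pk, d0, times) +
                 concentration_profile(pk, d2, times),
               tolerance = 1e-12)

  # a dose equal to ka == ke is handled by the documented perturbation
  pk_deg <- pk_params("one_compartment", ka = 0.5, CL = 30, V1 = 60, F = 1)
  h <- dosing_history(100, 5, taken = c(1, rep(0, 4)))
  expect_true(all(is.finite(concentration_profile(pk_deg, h, times))))
})

test_that("steady-state urate obeys the Emax-model identities", {
  pd <- test_pd(Imax = 0.8, IC50 = 2)
  base <- steady_state_urate(pd, 0)
  expect_gt(base, 0)

  # half-maximal inhibition at C = IC50: multiplier exactly 1 - Imax/2
  half <- steady_state_urate(pd, pd$IC50)
  I <- pd$Imax / 2
  k1 <- pd$k_hx_x * (1 - I); k2 <- pd$k_x_ua * (1 - I)
  manual <- pd$kin * (k1 / (k1 + pd$CLr_hx / pd$V_hx)) *
    (k2 / (k2 + pd$CLr_x / pd$V_x)) / (pd$CLr_ua / pd$V_ua) / pd$V_ua / 10
  expect_equal(half, manual, tolerance = 1e-12)

  # complete inhibition of both oxidase steps shuts off urate production
  pd_full <- test_pd(Imax = 1, IC50 = 1e-6)
  expect_lt(steady_state_urate(pd_full, 1e6), 1e-9)

  # stimulation of xanthine excretion lowers the steady state
  pd_s <- test_pd(Imax = 0, Emax_x = 1, EC50_x = 1)
  expect_lt(steady_state_urate(pd_s, 10), steady_state_urate(pd_s, 0))
})

test_that("baseline calibration is exact and linear in kin", {
  pd <- test_pd()
  cal8 <- calibrate_baseline(pd, 8)
  expect_equal(steady_state_urate(cal8, 0), 8, tolerance = 1e-9)
  cal16 <- calibrate_baseline(pd, 16)
  expect_equal(cal16$kin, 2 * cal8$kin, tolerance = 1e-12)

  # calibrated subject never dosed stays at baseline
  ua <- simulate_urate(cal8, 0, duration = 60)
  expect_true(all(abs(ua - 8) < 0.001 * 8))
})

test_that("simulated urate reaches the analytic steady state under constant exposure", {
  pd <- calibrate_baseline(test_pd(Imax = 0.9, IC50 = 2, Emax_x = 0.5,
                                   EC50_x = 2), 9)
  for (C in c(1, 4, 12)) {
    dur <- ceiling(10 * slowest_halflife(pd, C))
    ua <- simulate_urate(pd, C, duration = dur)
    target <- steady_state_urate(pd, C)
    expect_lt(abs(ua[dur] - target) / target, 0.01)
  }
})

test_that("a drug with no effect leaves sUA at baseline regardless of exposure", {
  pd <- calibrate_baseline(test_pd(Imax = 0, Emax_x = 0), 7.5)
  ua <- simulate_urate(pd, 50, duration = 40)
  expect_true(all(abs(ua - 7.5) < 0.001 * 7.5))
})

test_that("terminal sUA is non-increasing in dose", {
  pk <- test_pk1()
  pd <- calibrate_baseline(test_pd(Imax = 0.9, IC50 = 2), 9)
  finals <- vapply(c(0, 50, 100, 200, 400, 800), function(dose) {
    h <- dosing_history(dose, 60)
    ua <- simulate_urate(pd, function(t) concentration_profile(pk, h, t), 60)
    ua[60]
  }, 0)
  expect_true(all(diff(finals) <= 1e-8))
})

test_that("the compiled cohort integrator agrees with the reference ODE path", {
  set.seed(99)
  pk <- test_pk2()
  pd <- test_pd(Imax = 0.95, IC50 = 0.05, Emax_x = 1, EC50_x = 0.1)
  duration <- 28L
  n <- 5L
  baselines <- c(7, 8.5, 9, 10, 11)
  taken <- matrix(rbinom(duration * n, 1, 0.85), duration, n)
  mac <- ctsroi:::pk_macro_vec("two_compartment", rep(pk$ka, n), rep(pk$CL, n),
                               rep(pk$V1, n), rep(pk$Q, n), rep(pk$V2, n),
                               pk$F)
  kin <- vapply(baselines, function(b) calibrate_baseline(pd, b)$kin, 0)
  tr <- ctsroi:::cohort_troughs(mac$lambda, mac$coef, mac$nexp,
                                rep(80, n), taken, kin,
                                rep(pd$k_hx_x, n), rep(pd$k_x_ua, n),
                                rep(pd$CLr_hx / pd$V_hx, n),
                                rep(pd$CLr_x / pd$V_x, n),
                                rep(pd$CLr_ua / pd$V_ua, n),
                                rep(pd$V_ua, n), rep(pd$Imax, n),
                                rep(pd$IC50, n), rep(pd$Emax_x, n),
                                rep(pd$EC50_x, n), duration, 20L)
  for (i in seq_len(n)) {
    cal <- calibrate_baseline(pd, baselines[i])
    h <- dosing_history(80, duration, taken = taken[, i])
    ref <- simulate_urate(cal, function(t) concentration_profile(pk, h, t),
                          duration)
    expect_lt(max(abs(tr[, i] - ref) / ref), 5e-3)
  }
})
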