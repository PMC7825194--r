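#' Markov cost-effectiveness model specification
#'
#' Cohort state-transition model with three serum-uric-acid bands
#' (`< 6`, `6-8`, `> 8` mg/dL) plus death, a 3-month cycle and a 50-year
#' (lifetime) horizon. Each band carries an annual gout-flare rate, a cost
#' per flare, a per-state utility and a per-flare disutility; band-level
#' management costs accrue per year alive. Patients start on treatment and
#' discontinue according to the same Weibull model used in the trial
#' simulation; on discontinuation they revert to the untreated sUA
#' distribution (the non-responder split across the two upper bands). Costs
#' and QALYs are discounted at `discount_annual` per annum with cycle-start
#' discounting and no half-cycle correction.
#'
#' @param cycle_years Cycle length (years).
#' @param horizon_years Time horizon (years).
#' @param discount_annual Annual discount rate for costs and QALYs.
#' @param flare_rate_annual Length-3 vector of annual flare rates per band.
#' @param flare_cost Cost per flare (GBP).
#' @param utility Length-3 vector of per-band utilities in `[0, 1]`.
#' @param flare_disutility QALY loss per flare.
#' @param care_cost_annual Length-3 vector of annual management costs (GBP).
#' @param mortality_annual Annual background death probability.
#' @param nonresponder_split Length-2 split of non-responders (and of
#'   patients off treatment) across the `6-8` and `> 8` bands; sums to 1.
#' @param dropout_shape,dropout_scale_days Weibull discontinuation parameters
#'   (shape dimensionless, scale in days; `Inf` disables discontinuation).
#' @param comparator_price_annual Annual drug cost of the comparator (GBP).
#' @param days_per_year Calendar conversion used for the Weibull time scale.
#' @return An object of class `markov_spec`.
#' @export
markov_spec <- function(cycle_years = 0.25, horizon_years = 50,
                        discount_annual = 0.035,
                        flare_rate_annual = c(0.35, 1.2, 2.5),
                        flare_cost = 250,
                        utility = c(0.87, 0.82, 0.76),
                        flare_disutility = 0.012,
                        care_cost_annual = c(150, 200, 300),
                        mortality_annual = 0.02,
                        nonresponder_split = c(0.5, 0.5),
                        dropout_shape = 0.5, dropout_scale_days = 7000,
                        comparator_price_annual = 30,
                        days_per_year = 365.25) {
  check_positive(cycle_years, "cycle_years")
  check_positive(horizon_years, "horizon_years")
  check_scalar(discount_annual, "discount_annual", lower = 0)
  if (length(flare_rate_annual) != 3 || any(flare_rate_annual < 0))
    abort_input("'flare_rate_annual' must be 3 non-negative rates")
  if (length(utility) != 3 || any(utility < 0 | utility > 1))
    abort_input("'utility' must be 3 values in [0, 1]")
  if (length(care_cost_annual) != 3 || any(care_cost_annual < 0))
    abort_input("'care_cost_annual' must be 3 non-negative costs")
  check_scalar(flare_cost, "flare_cost", lower = 0)
  check_scalar(flare_disutility, "flare_disutility", lower = 0)
  check_scalar(mortality_annual, "mortality_annual", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (length(nonresponder_split) != 2 || any(nonresponder_split < 0) ||
      abs(sum(nonresponder_split) - 1) > 1e-12)
    abort_input("'nonresponder_split' must be 2 non-negative shares summing to 1")
  check_positive(dropout_shape, "dropout_shape")
  check_scalar(dropout_scale_days, "dropout_scale_days", lower = 0,
               strict_lower = TRUE, allow_inf = TRUE)
  check_scalar(comparator_price_annual, "comparator_price_annual", lower = 0)
  check_positive(days_per_year, "days_per_year")
  structure(list(cycle_years = cycle_years, horizon_years = horizon_years,
                 discount_annual = discount_annual,
                 flare_rate_annual = flare_rate_annual,
                 flare_cost = flare_cost, utility = utility,
                 flare_disutility = flare_disutility,
                 care_cost_annual = care_cost_annual,
                 mortality_annual = mortality_annual,
                 nonresponder_split = nonresponder_split,
                 dropout_shape = dropout_shape,
                 dropout_scale_days = dropout_scale_days,
                 comparator_price_annual = comparator_price_annual,
                 days_per_year = days_per_year),
            class = "markov_spec")
}

#' Initial state occupancy from a trial response rate
#'
#' Responders enter the `< 6 mg/dL` band; non-responders are split across
#' the `6-8` and `> 8` bands.
#'
#' @param theta Responder proportion in `[0, 1]`.
#' @param split Length-2 non-responder split (sums to 1).
#' @return Named occupancy vector `(lt6, b6_8, gt8, dead)` summing to 1.
#' @export
#' @examples
#' build_cohort_start(0.36)  # c(0.36, 0.32, 0.32, 0)
build_cohort_start <- function(theta, split = c(0.5, 0.5)) {
  check_scalar(theta, "theta", lower = 0, upper = 1)
  if (length(split) != 2 || any(split < 0) || abs(sum(split) - 1) > 1e-12)
    abort_input("'split' must be 2 non-negative shares summing to 1")
  c(lt6 = theta, b6_8 = (1 - theta) * split[1],
    gt8 = (1 - theta) * split[2], dead = 0)
}

# Weibull survival-on-treatment at t years.
treatment_survival <- function(spec, t_years) {
  if (!is.finite(spec$dropout_scale_days)) return(rep(1, length(t_years)))
  exp(-((t_years * spec$days_per_year) / spec$dropout_scale_days)^spec$dropout_shape)
}

# 6 x 6 single-cycle transition matrix at cycle index i (0-based). States:
# on-treatment bands 1-3, off-treatment upper bands (6-8, > 8), dead.
# Discontinued patients revert to the untreated sUA distribution, so the
# off-treatment < 6 band is unreachable and carries no state. Validated to
# have unit row sums; time-varying because the Weibull discontinuation
# hazard falls over time.
cycle_transition_matrix <- function(spec, i) {
  t0 <- i * spec$cycle_years
  t1 <- t0 + spec$cycle_years
  s0 <- treatment_survival(spec, t0)
  s1 <- treatment_survival(spec, t1)
  p_dc <- if (s0 > 0) 1 - s1 / s0 else 1
  q <- 1 - (1 - spec$mortality_annual)^spec$cycle_years
  sp <- spec$nonresponder_split
  T <- matrix(0, 6, 6)
  for (b in 1:3) {
    T[b, b] <- (1 - q) * (1 - p_dc)
    T[b, 4] <- (1 - q) * p_dc * sp[1]
    T[b, 5] <- (1 - q) * p_dc * sp[2]
    T[b, 6] <- q
  }
  T[4, 4] <- T[5, 5] <- 1 - q
  T[4, 6] <- T[5, 6] <- q
  T[6, 6] <- 1
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-12))
    abort_input("transition matrix rows must sum to 1 (max deviation %g)",
                max(abs(rs - 1)))
  T
}

#' Run the Markov cohort model
#'
#' Propagates the cohort over `horizon / cycle` cycles, accumulating
#' discounted QALYs, discounted non-drug costs and discounted person-years on
#' treatment (`t2`). Occupancy (including death) is conserved at every cycle.
#' Drug acquisition cost is deliberately excluded so the caller can attach
#' any price `P` as `P * t2`.
#'
#' @param spec A [markov_spec()].
#' @param start Length-4 occupancy `(lt6, b6_8, gt8, dead)` summing to 1;
#'   see [build_cohort_start()]. The alive mass starts on treatment.
#' @return An `econ_outcome`: `Q` (QALYs), `C_nondrug` (GBP), `t2` (years),
#'   and the `trace` matrix (cycle x 6 states: three on-treatment bands, the
#'   two off-treatment upper bands, dead).
#' @export
run_markov <- function(spec, start) {
  stopifnot(inherits(spec, "markov_spec"))
  if (length(start) != 4 || any(start < 0) || abs(sum(start) - 1) > 1e-8)
    abort_input("'start' must be a length-4 occupancy summing to 1")
  ncyc <- round(spec$horizon_years / spec$cycle_years)
  occ <- c(start[1:3], 0, 0, start[4])
  trace <- matrix(NA_real_, ncyc + 1, 6,
                  dimnames = list(NULL, c("on_lt6", "on_b6_8", "on_gt8",
                                          "off_b6_8", "off_gt8", "dead")))
  trace[1, ] <- occ
  dt <- spec$cycle_years
  band_u <- spec$utility * dt - spec$flare_rate_annual * dt * spec$flare_disutility
  band_c <- (spec$care_cost_annual + spec$flare_rate_annual * spec$flare_cost) * dt
  Q <- 0; Cn <- 0; t2 <- 0
  for (i in seq_len(ncyc) - 1L) {
    df <- (1 + spec$discount_annual)^(-i * dt)
    alive_bands <- occ[1:3] + c(0, occ[4], occ[5])  # off states map to bands 2,3
    Q <- Q + sum(alive_bands * band_u) * df
    Cn <- Cn + sum(alive_bands * band_c) * df
    t2 <- t2 + sum(occ[1:3]) * dt * df
    Tm <- cycle_transition_matrix(spec, i)
    occ <- as.numeric(occ %*% Tm)
    if (abs(sum(occ) - 1) > 1e-12)
      abort_input("occupancy not conserved at cycle %d", i + 1)
    trace[i + 2, ] <- occ
  }
  structure(list(Q = Q, C_nondrug = Cn, t2 = t2, trace = trace, spec = spec),
            class = "econ_outcome")
}

#' Incremental net monetary benefit
#'
#' `lambda * (Q2 - Q1) - (C2 - C1)` for willingness-to-pay threshold
#' `lambda` (GBP per QALY).
#'
#' @param Q1,C1 Discounted QALYs and total cost of the comparator strategy.
#' @param Q2,C2 Discounted QALYs and total cost of the new-treatment strategy.
#' @param lambda Cost-effectiveness threshold (GBP/QALY).
#' @return Net monetary benefit (GBP).
#' @export
nmb <- function(Q1, C1, Q2, C2, lambda) {
  check_positive(lambda, "lambda")
  lambda * (Q2 - Q1) - (C2 - C1)
}

#' Expected discounted years of persistence with treatment
#'
#' Discounted person-years on treatment under the Weibull discontinuation
#' model. `method = "cycle"` uses the same cycle-start sum as the Markov
#' trace (`sum S(t_i) * dt * disc(t_i)`), excluding background mortality;
#' `method = "exact"` integrates `S(t) * (1 + r)^(-t)` numerically and is the
#' continuous-time limit.
#'
#' @param shape,scale_days Weibull discontinuation parameters.
#' @param horizon_years Treatment horizon (years).
#' @param discount_annual Annual discount rate.
#' @param cycle_years Cycle length for `method = "cycle"`.
#' @param method `"cycle"` or `"exact"`.
#' @param days_per_year Calendar conversion.
#' @return Discounted years on treatment, in `(0, horizon_years]`.
#' @export
expected_persistence <- function(shape, scale_days, horizon_years,
                                 discount_annual = 0, cycle_years = 0.25,
                                 method = c("cycle", "exact"),
                                 days_per_year = 365.25) {
  method <- match.arg(method)
  check_positive(shape, "shape")
  check_scalar(scale_days, "scale_days", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  check_positive(horizon_years, "horizon_years")
  check_scalar(discount_annual, "discount_annual", lower = 0)
  surv <- function(t) {
    if (!is.finite(scale_days)) rep(1, length(t))
    else exp(-((t * days_per_year) / scale_days)^shape)
  }
  disc <- function(t) (1 + discount_annual)^(-t)
  if (method == "cycle") {
    ti <- seq(0, horizon_years - cycle_years, by = cycle_years)
    sum(surv(ti) * cycle_years * disc(ti))
  } else {
    integrate(function(t) surv(t) * disc(t), 0, horizon_years,
              rel.tol = 1e-10, subdivisions = 2000L)$value
  }
}

#' Maximum reimbursement price
#'
#' The annual price of the new treatment at which the incremental net
#' monetary benefit is exactly zero:
#' `P2 = (C1 - C2_nondrug + lambda * (Q2 - Q1)) / t2`, where `t2` is the
#' expected discounted years on the new treatment. Substituting the drug
#' cost `P2 * t2` back into the NMB returns zero by construction.
#'
#' @param C1 Total discounted cost of the comparator strategy (GBP),
#'   including the comparator's drug cost.
#' @param C2_nondrug Discounted non-drug cost of the new-treatment strategy.
#' @param Q1,Q2 Discounted QALYs per strategy.
#' @param lambda Cost-effectiveness threshold (GBP/QALY).
#' @param t2 Expected discounted years on the new treatment (`> 0`).
#' @return Annual price (GBP); may be negative when the new treatment is
#'   dominated.
#' @export
max_reimbursement_price <- function(C1, C2_nondrug, Q1, Q2, lambda, t2) {
  check_positive(lambda, "lambda")
  if (!is.numeric(t2) || any(t2 <= 0)) abort_input("'t2' must be positive")
  (C1 - C2_nondrug + lambda * (Q2 - Q1)) / t2
}
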