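#' Return-on-investment cost inputs
#'
#' Sponsor-side inputs of the payoff model: fixed and per-subject trial
#' costs, the per-patient-year cost of production and marketing, and the
#' minimum viable annual price below which development is terminated.
#'
#' @param trial_fixed_cost Fixed trial cost (GBP).
#' @param trial_variable_cost Cost per enrolled subject (GBP).
#' @param production_marketing Production and marketing cost per patient-year
#'   (GBP).
#' @param minimum_price Minimum acceptable annual price (GBP).
#' @return An object of class `roi_inputs`.
#' @export
roi_inputs <- function(trial_fixed_cost = 5e6, trial_variable_cost = 2e4,
                       production_marketing = 10, minimum_price = 70) {
  for (nm in c("trial_fixed_cost", "trial_variable_cost",
               "production_marketing", "minimum_price")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  structure(list(trial_fixed_cost = trial_fixed_cost,
                 trial_variable_cost = trial_variable_cost,
                 production_marketing = production_marketing,
                 minimum_price = minimum_price),
            class = "roi_inputs")
}

#' Market model for future drug sales
#'
#' The number of patients treated over the market horizon is
#' `annual_incidence * uptake * horizon_years`, halved when the trial's
#' inclusion threshold is at or above `halving_threshold` (a stricter sUA
#' threshold for treatment halves the eligible population).
#'
#' @param annual_incidence Newly eligible patients per year.
#' @param horizon_years Market horizon H (years).
#' @param uptake Fraction of eligible patients treated, in `[0, 1]`.
#' @param halving_threshold Inclusion threshold (mg/dL) at which the eligible
#'   population is halved; `NULL` disables the rule.
#' @return An object of class `market_model`.
#' @export
market_model <- function(annual_incidence = 15000, horizon_years = 10,
                         uptake = 1, halving_threshold = 8) {
  check_scalar(annual_incidence, "annual_incidence", lower = 0)
  check_scalar(horizon_years, "horizon_years", lower = 0)
  check_scalar(uptake, "uptake", lower = 0, upper = 1)
  if (!is.null(halving_threshold)) check_positive(halving_threshold, "halving_threshold")
  structure(list(annual_incidence = annual_incidence,
                 horizon_years = horizon_years, uptake = uptake,
                 halving_threshold = halving_threshold),
            class = "market_model")
}

#' Patients reached over the market horizon
#'
#' @param market A [market_model()].
#' @param inclusion_threshold The trial design's inclusion threshold (mg/dL).
#' @return Patient count `S(H)`.
#' @export
#' @examples
#' m <- market_model(20000, 10, 1)
#' market_size(m, 6)  # 200000
#' market_size(m, 8)  # 100000
market_size <- function(market, inclusion_threshold) {
  stopifnot(inherits(market, "market_model"))
  check_positive(inclusion_threshold, "inclusion_threshold")
  S <- market$annual_incidence * market$uptake * market$horizon_years
  if (!is.null(market$halving_threshold) &&
      inclusion_threshold >= market$halving_threshold) {
    S <- S / 2
  }
  S
}

#' Total trial cost
#'
#' Fixed cost plus the per-subject cost times the total enrolment (both arms).
#'
#' @param total_n Total subjects across arms.
#' @param inputs An [roi_inputs()].
#' @return Trial cost (GBP).
#' @export
trial_cost <- function(total_n, inputs) {
  stopifnot(inherits(inputs, "roi_inputs"))
  check_scalar(total_n, "total_n", lower = 0)
  inputs$trial_fixed_cost + inputs$trial_variable_cost * total_n
}

#' Return on investment for one priced outcome
#'
#' If the maximum reimbursement price reaches the sponsor's minimum,
#' `ROI = (P2 - C_PM) * t2 * S - C_trial`; otherwise development is
#' terminated and the ROI is exactly zero (no revenue and no sunk trial
#' cost). The boundary `P2 == P_min` launches. Vectorized over `P2`.
#'
#' @param P2 Annual price (GBP); typically the maximum reimbursement price.
#' @param t2 Expected discounted years on treatment per patient.
#' @param S Patients reached over the market horizon.
#' @param Ctrial Total trial cost (GBP).
#' @param inputs An [roi_inputs()].
#' @return ROI (GBP), same length as `P2`.
#' @export
roi_single <- function(P2, t2, S, Ctrial, inputs) {
  stopifnot(inherits(inputs, "roi_inputs"))
  ifelse(P2 >= inputs$minimum_price,
         (P2 - inputs$production_marketing) * t2 * S - Ctrial,
         0)
}

# Preposterior draws shared across the sample-size grid (common random
# numbers): theta_j and a binomial quantile-coupling uniform are drawn once
# per replicate, then m = qbinom(u, n, theta) for every n. This couples the
# grid points, reducing Monte Carlo noise in ROI differences across n, and
# makes results independent of which subset of the grid is evaluated.
preposterior_draws <- function(prior1, prior2, R, seed) {
  withr::with_seed(as.integer(seed), {
    list(theta1 = rbeta(R, prior1$alpha, prior1$beta),
         theta2 = rbeta(R, prior2$alpha, prior2$beta),
         u1 = runif(R), u2 = runif(R))
  })
}

# Economic outcomes as affine functions of theta: the Markov model is linear
# in the start occupancy, so one run per pure start (all-responder /
# all-non-responder) determines Q(theta) and C(theta) exactly.
econ_linearization <- function(spec) {
  E1 <- run_markov(spec, build_cohort_start(1, spec$nonresponder_split))
  E0 <- run_markov(spec, build_cohort_start(0, spec$nonresponder_split))
  list(Q = function(th) th * E1$Q + (1 - th) * E0$Q,
       Cn = function(th) th * E1$C_nondrug + (1 - th) * E0$C_nondrug,
       t2 = E1$t2)
}

#' Replicate-level design evaluation at one or more sample sizes
#'
#' Draws proposed trial data from the prior predictive distribution for both
#' arms, performs the conjugate update, maps the posterior point estimates
#' through the Markov model (using its linearity in the start occupancy) and
#' computes the maximum reimbursement price for every replicate.
#'
#' @param prior1,prior2 [beta_dist()] priors for the comparator and new
#'   treatment arms.
#' @param n_grid Per-arm sample sizes (positive, strictly increasing).
#' @param R Number of preposterior replicates.
#' @param seed Integer seed.
#' @param econ A [markov_spec()].
#' @param lambda Cost-effectiveness threshold (GBP/QALY).
#' @param point `"mean"` feeds the posterior mean downstream; `"sample"`
#'   draws one value from each posterior instead (an uncertainty-averse
#'   payer).
#' @return A data frame with one row per (n, replicate): draws, posterior
#'   point estimates and `P2`.
#' @export
evaluate_design <- function(prior1, prior2, n_grid, R, seed, econ,
                            lambda = 20000, point = c("mean", "sample")) {
  stopifnot(inherits(prior1, "beta_dist"), inherits(prior2, "beta_dist"),
            inherits(econ, "markov_spec"))
  point <- match.arg(point)
  check_scalar(R, "R", lower = 1)
  if (any(n_grid < 1) || any(diff(n_grid) <= 0))
    abort_input("'n_grid' must be positive and strictly increasing")
  R <- as.integer(R)
  draws <- preposterior_draws(prior1, prior2, R, seed)
  post_seed <- if (point == "sample") derive_seeds(seed, 1L) + 1L else NULL
  lin <- econ_linearization(econ)
  t2 <- lin$t2
  P1 <- econ$comparator_price_annual
  out <- vector("list", length(n_grid))
  for (k in seq_along(n_grid)) {
    n <- as.integer(n_grid[k])
    m1 <- qbinom(draws$u1, n, draws$theta1)
    m2 <- qbinom(draws$u2, n, draws$theta2)
    a1 <- prior1$alpha + m1; b1 <- prior1$beta + n - m1
    a2 <- prior2$alpha + m2; b2 <- prior2$beta + n - m2
    if (point == "mean") {
      th1 <- a1 / (a1 + b1)
      th2 <- a2 / (a2 + b2)
    } else {
      us <- withr::with_seed(post_seed + k, list(runif(R), runif(R)))
      th1 <- qbeta(us[[1]], a1, b1)
      th2 <- qbeta(us[[2]], a2, b2)
    }
    Q1 <- lin$Q(th1); Q2 <- lin$Q(th2)
    C1 <- lin$Cn(th1) + P1 * t2
    C2n <- lin$Cn(th2)
    P2 <- max_reimbursement_price(C1, C2n, Q1, Q2, lambda, t2)
    out[[k]] <- data.frame(n = n, replicate = seq_len(R),
                           theta1 = draws$theta1, theta2 = draws$theta2,
                           m1 = m1, m2 = m2, post1 = th1, post2 = th2,
                           Q1 = Q1, Q2 = Q2, C1 = C1, C2_nondrug = C2n,
                           t2 = t2, P2 = P2)
  }
  do.call(rbind, out)
}

#' Expected return on investment over the sample-size grid
#'
#' Monte Carlo expectation of the ROI over the prior predictive distribution
#' of trial outcomes, per per-arm sample size, with the optimal size flagged
#' (ties broken towards the smallest, i.e. cheapest, trial).
#'
#' @inheritParams evaluate_design
#' @param roi An [roi_inputs()].
#' @param market A [market_model()].
#' @param inclusion_threshold The design's inclusion threshold (mg/dL),
#'   consumed by the market-halving rule.
#' @return An `roi_table` data frame: `n`, `expected_roi`, `p_termination`
#'   (probability that `P2 < P_min`), `optimal`.
#' @export
expected_roi <- function(prior1, prior2, n_grid, R, seed, econ, roi, market,
                         inclusion_threshold, lambda = 20000,
                         point = c("mean", "sample")) {
  stopifnot(inherits(roi, "roi_inputs"), inherits(market, "market_model"))
  ev <- evaluate_design(prior1, prior2, n_grid, R, seed, econ, lambda, point)
  S <- market_size(market, inclusion_threshold)
  rows <- lapply(split(ev, ev$n), function(d) {
    n <- d$n[1]
    r <- roi_single(d$P2, d$t2, S, trial_cost(2 * n, roi), roi)
    data.frame(n = n, expected_roi = mean(r),
               p_termination = mean(d$P2 < roi$minimum_price))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n), , drop = FALSE]
  rownames(out) <- NULL
  out$optimal <- seq_len(nrow(out)) == which.max(out$expected_roi)
  class(out) <- c("roi_table", "data.frame")
  out
}
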