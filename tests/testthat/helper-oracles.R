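# Independent numerical oracles, deliberately kept apart from the package's
# own computational paths.

# Numerical ODE solution of the absorption/disposition system for a single
# oral dose at t = 0 (oracle for the closed-form concentration profile).
ode_concentration <- function(pk, dose, times) {
  if (pk$model == "one_compartment") {
    y0 <- c(gut = dose * pk$F, central = 0)
    rhs <- function(t, y, p) {
      list(c(-pk$ka * y[1], pk$ka * y[1] - pk$CL / pk$V1 * y[2]))
    }
  } else {
    y0 <- c(gut = dose * pk$F, central = 0, periph = 0)
    rhs <- function(t, y, p) {
      list(c(-pk$ka * y[1],
             pk$ka * y[1] - (pk$CL + pk$Q) / pk$V1 * y[2] + pk$Q / pk$V2 * y[3],
             pk$Q / pk$V1 * y[2] - pk$Q / pk$V2 * y[3]))
    }
  }
  sol <- deSolve::lsoda(y0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  sol[, "central"] / pk$V1
}

# Brute-force grid posterior for the Beta-binomial model: likelihood x prior
# density on an equally spaced theta grid, trapezoid-normalized.
grid_posterior <- function(prior, m, n, npts = 2001L) {
  theta <- seq(0, 1, length.out = npts)
  logd <- stats::dbeta(theta, prior$alpha, prior$beta, log = TRUE) +
    stats::dbinom(m, n, theta, log = TRUE)
  d <- exp(logd - max(logd[is.finite(logd)]))
  d[!is.finite(d)] <- 0
  h <- theta[2] - theta[1]
  w <- rep(h, npts); w[c(1, npts)] <- h / 2  # trapezoid weights
  Z <- sum(d * w)
  f <- d / Z
  mean_ <- sum(theta * f * w)
  cdf <- cumsum(f * w) - f * w / 2
  qfun <- function(p) stats::approx(cdf, theta, xout = p, ties = "ordered")$y
  list(mean = mean_, q2.5 = qfun(0.025), q97.5 = qfun(0.975))
}

# Closed-form discrete annuity: sum of c * dt * (1 + r)^(-i dt), i = 0..k-1.
discounted_annuity <- function(c_per_year, dt, r, ncycles) {
  g <- (1 + r)^(-dt)
  if (r == 0) return(c_per_year * dt * ncycles)
  c_per_year * dt * (1 - g^ncycles) / (1 - g)
}
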