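#' Beta distribution
#'
#' The conjugate prior/posterior family for the binomial trial outcome.
#'
#' @param alpha,beta Strictly positive, finite shape parameters.
#' @return An object of class `beta_dist`.
#' @export
beta_dist <- function(alpha, beta) {
  check_positive(alpha, "alpha")
  check_positive(beta, "beta")
  structure(list(alpha = alpha, beta = beta), class = "beta_dist")
}

#' @export
print.beta_dist <- function(x, ...) {
  cat(sprintf("Beta(alpha = %.6g, beta = %.6g): mean %.4f, sd %.4f\n",
              x$alpha, x$beta, beta_mean(x), sqrt(beta_var(x))))
  invisible(x)
}

beta_mean <- function(b) b$alpha / (b$alpha + b$beta)
beta_var <- function(b) {
  s <- b$alpha + b$beta
  b$alpha * b$beta / (s^2 * (s + 1))
}

#' Conjugate Beta-binomial posterior update
#'
#' With prior `Beta(alpha, beta)` and `m` responders out of `n` subjects, the
#' posterior is `Beta(alpha + m, beta + n - m)`.
#'
#' @param prior A [beta_dist()].
#' @param m Responder count (integer, `0 <= m <= n`).
#' @param n Arm sample size (integer, `>= 0`).
#' @return The posterior [beta_dist()].
#' @export
#' @examples
#' posterior_update(beta_dist(7.1, 12.4), m = 36, n = 100)
posterior_update <- function(prior, m, n) {
  stopifnot(inherits(prior, "beta_dist"))
  check_scalar(n, "n", lower = 0)
  check_scalar(m, "m", lower = 0, upper = n)
  if (m != round(m) || n != round(n))
    abort_input("'m' and 'n' must be integers")
  beta_dist(prior$alpha + m, prior$beta + n - m)
}

#' Draw proposed trial data from the prior predictive distribution
#'
#' Draws the true response rate `theta` from the prior, then the responder
#' count `m ~ Binomial(n, theta)`.
#'
#' @param prior A [beta_dist()].
#' @param n Arm sample size.
#' @param seed Optional integer seed; omit to use the ambient RNG state.
#' @return `list(theta =, m =, n =)`.
#' @export
prior_predictive_draw <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "beta_dist"))
  check_scalar(n, "n", lower = 1)
  maybe_with_seed(seed, {
    theta <- rbeta(1, prior$alpha, prior$beta)
    m <- rbinom(1, as.integer(n), theta)
    list(theta = theta, m = m, n = as.integer(n))
  })
}

#' Posterior point estimate fed to the economic model
#'
#' The posterior mean `alpha / (alpha + beta)`: reimbursement decisions are
#' taken on expected values, so the expectation of the response rate is the
#' default summary passed downstream.
#'
#' @param posterior A [beta_dist()].
#' @return Proportion in (0, 1).
#' @export
posterior_point <- function(posterior) {
  stopifnot(inherits(posterior, "beta_dist"))
  beta_mean(posterior)
}
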