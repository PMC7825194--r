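#' Parameter-uncertainty specification
#'
#' Coefficients of variation (CVs) for the population PK/PD parameters, used
#' to propagate input uncertainty through the clinical trial simulation by
#' multiplicative lognormal perturbation (a constant-CV model). `cv_pk` and
#' `cv_effect` apply to every drug's PK block and drug-effect block; the
#' shared uric-acid physiology is perturbed once per replicate through
#' `cv_system`, so both arms see the same physiological draw.
#'
#' @param cv_pk,cv_effect,cv_system Named non-negative numeric vectors of CVs
#'   keyed by parameter name; parameters not named are left unperturbed.
#' @param scenario `"base_case"` or `"reduced"`.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(cv_pk, cv_effect, cv_system,
                             scenario = c("base_case", "reduced")) {
  scenario <- match.arg(scenario)
  for (v in list(cv_pk, cv_effect, cv_system)) {
    if (length(v) && (is.null(names(v)) || any(unlist(v) < 0)))
      abort_input("CV vectors must be named and non-negative")
  }
  structure(list(cv_pk = unlist(cv_pk), cv_effect = unlist(cv_effect),
                 cv_system = unlist(cv_system), scenario = scenario),
            class = "uncertainty_spec")
}

# One lognormal multiplier with exact coefficient of variation cv.
lognormal_factor <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, 0, sdlog))
}

#' Perturb population parameters under a constant-CV model
#'
#' Each parameter with a configured CV is multiplied by `exp(eta)` with
#' `eta ~ Normal(0, log(1 + cv^2))`, so the perturbed parameter has exactly
#' the configured coefficient of variation and positivity is preserved.
#' Draws follow a fixed order (system block, then each drug's PK and effect
#' blocks), which makes the perturbation reproducible under a seed.
#'
#' @param params Population parameter set: `list(system = <named list>,
#'   drugs = list(<name> = list(pk = pk_params, effect = <named list>,
#'   iiv = <named vector>)))`.
#' @param spec An [uncertainty_spec()].
#' @param seed Integer seed.
#' @return The perturbed parameter set (same structure).
#' @export
perturb_parameters <- function(params, spec, seed) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  withr::with_seed(as.integer(seed), {
    for (nm in names(params$system)) {
      cv <- spec$cv_system[nm]
      if (!is.na(cv) && cv > 0)
        params$system[[nm]] <- params$system[[nm]] * lognormal_factor(1, cv)
    }
    for (dn in names(params$drugs)) {
      pk <- params$drugs[[dn]]$pk
      for (nm in intersect(names(spec$cv_pk), names(pk))) {
        cv <- spec$cv_pk[nm]
        if (cv > 0 && !is.null(pk[[nm]]))
          pk[[nm]] <- pk[[nm]] * lognormal_factor(1, cv)
      }
      params$drugs[[dn]]$pk <- pk
      eff <- params$drugs[[dn]]$effect
      for (nm in intersect(names(spec$cv_effect), names(eff))) {
        cv <- spec$cv_effect[nm]
        if (cv > 0)
          eff[[nm]] <- eff[[nm]] * lognormal_factor(1, cv)
      }
      params$drugs[[dn]]$effect <- eff
    }
    params
  })
}

assemble_arm_params <- function(params, drug) {
  d <- params$drugs[[drug]]
  if (is.null(d)) abort_input("no parameter block for drug '%s'", drug)
  pk <- do.call(pk_params,
                d$pk[intersect(c("model", "ka", "CL", "V1", "Q", "V2", "F"),
                               names(d$pk))])
  pd <- do.call(pd_params, c(params$system, d$effect))
  list(pk = pk, pd = pd, iiv = d$iiv)
}

#' Run the clinical trial simulation for one design
#'
#' Replicates the trial `R` times. Each replicate perturbs the population
#' parameters under the design's uncertainty scenario, assembles fresh
#' post-inclusion cohorts of `N` subjects per arm, simulates both arms, and
#' records the per-arm response rates. Within a replicate both arms share the
#' same physiological (system) parameter draw but have drug-specific PK and
#' effect draws. Replicate failures are recorded and excluded; more than 1%
#' failures is an error.
#'
#' @param design A [trial_design()].
#' @param params Population parameter set (see [perturb_parameters()]).
#' @param pop A [population_spec()].
#' @param adh An [adherence_params()].
#' @param spec The [uncertainty_spec()] for the design's scenario.
#' @param R Number of replicates (`>= 2`).
#' @param N Post-inclusion subjects per arm per replicate.
#' @param seed Master seed for this run.
#' @param cmod A [covariate_model()].
#' @param resample_cohort Draw a fresh cohort every replicate (default); if
#'   `FALSE` a single cohort per arm is reused across replicates so that only
#'   parameter uncertainty is propagated.
#' @return A `cts_result`: `theta` (`R x 2` matrix of response rates, columns
#'   named by drug), the design, and bookkeeping fields.
#' @export
run_cts <- function(design, params, pop, adh, spec, R, N, seed,
                    cmod = covariate_model(), resample_cohort = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  check_scalar(R, "R", lower = 2)
  check_scalar(N, "N", lower = 1)
  R <- as.integer(R)
  N <- as.integer(N)
  drugs <- vapply(design$arms, `[[`, "", "drug")
  seeds <- derive_seeds(seed, R)
  theta <- matrix(NA_real_, R, 2, dimnames = list(NULL, drugs))
  fixed_cohorts <- NULL
  if (!resample_cohort) {
    cs <- derive_seeds(derive_seeds(seed, 1L) + 1L, 2L)
    fixed_cohorts <- lapply(1:2, function(a) {
      ap <- assemble_arm_params(params, drugs[a])
      sample_included_cohort(pop, N, design$inclusion_threshold, cs[a],
                             ap$iiv, adh)
    })
  }
  failures <- character(0)
  for (r in seq_len(R)) {
    sub <- derive_seeds(seeds[r], 5L)
    res <- tryCatch({
      pr <- perturb_parameters(params, spec, sub[1])
      th <- numeric(2)
      for (a in 1:2) {
        ap <- assemble_arm_params(pr, drugs[a])
        cohort <- if (resample_cohort) {
          sample_included_cohort(pop, N, design$inclusion_threshold,
                                 sub[1 + a], ap$iiv, adh)
        } else {
          fixed_cohorts[[a]]
        }
        arm_res <- simulate_arm(design, a, cohort, ap$pk, ap$pd, adh,
                                seed = sub[3 + a], cmod = cmod)
        th[a] <- response_rate(arm_res)
      }
      th
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      theta[r, ] <- res
    }
  }
  if (length(failures) > 0.01 * R) {
    abort_input("CTS failed in %d of %d replicates; first: %s",
                length(failures), R, failures[1])
  }
  theta <- theta[stats::complete.cases(theta), , drop = FALSE]
  structure(list(design = design, theta = theta, replicates = R,
                 subjects_per_arm = N, seed = as.integer(seed),
                 scenario = spec$scenario, failures = failures),
            class = "cts_result")
}

#' Summarize simulated response distributions into Beta priors
#'
#' For each arm: mean, sample SD (denominator `R - 1`) and empirical
#' 2.5th/97.5th percentiles (order statistics with linear interpolation) of
#' the replicate response rates, reported as percentages, plus the
#' moment-matched Beta shape parameters from [fit_beta_moments()]. Degenerate
#' samples (zero spread, or spread too large for a Beta with the same mean)
#' get `NA` shape parameters and a `degenerate` flag instead of an error.
#'
#' @param cts A `cts_result` from [run_cts()].
#' @return A `prior_summary` data frame, one row per arm.
#' @export
summarize_cts <- function(cts) {
  stopifnot(inherits(cts, "cts_result"))
  theta <- cts$theta
  if (nrow(theta) < 2L) abort_input("need at least two replicates to summarize")
  rows <- lapply(seq_len(ncol(theta)), function(a) {
    x <- theta[, a]
    m <- mean(x)
    s <- sd(x)
    q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    fit <- tryCatch(fit_beta_moments(m, s), error = function(e) NULL)
    data.frame(design_id = cts$design$design_id, scenario = cts$scenario,
               arm = a, drug = colnames(theta)[a],
               mean_pct = 100 * m, sd_pct = 100 * s,
               p2.5_pct = 100 * q[1], p97.5_pct = 100 * q[2],
               alpha = if (is.null(fit)) NA_real_ else fit$alpha,
               beta = if (is.null(fit)) NA_real_ else fit$beta,
               degenerate = is.null(fit))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prior_summary", "data.frame")
  out
}

#' Moment-matched Beta distribution
#'
#' Solves for the Beta shape parameters with the given mean and SD:
#' `nu = mean * (1 - mean) / sd^2 - 1`, `alpha = mean * nu`,
#' `beta = (1 - mean) * nu`. The fit is exact: the returned Beta has the
#' input mean and SD to machine precision.
#'
#' @param mean Mean response proportion, strictly inside (0, 1).
#' @param sd Standard deviation (proportion scale); must satisfy
#'   `sd^2 < mean * (1 - mean)`.
#' @return A [beta_dist()].
#' @export
#' @examples
#' fit_beta_moments(0.3, 0.1)  # Beta(6, 14)
fit_beta_moments <- function(mean, sd) {
  check_scalar(mean, "mean", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_positive(sd, "sd")
  v <- sd^2
  if (v >= mean * (1 - mean))
    abort_input("infeasible moments: sd^2 = %g >= mean*(1-mean) = %g",
                v, mean * (1 - mean))
  nu <- mean * (1 - mean) / v - 1
  beta_dist(mean * nu, (1 - mean) * nu)
}
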