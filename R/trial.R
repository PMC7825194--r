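#' Two-arm trial design
#'
#' The unit of comparison of the framework: a pair of once-daily regimens, a
#' trial duration, a minimum baseline sUA for inclusion, and the input
#' uncertainty scenario under which the design is simulated.
#'
#' @param design_id Short identifier, e.g. `"psi1"`.
#' @param arms List of exactly two `list(drug =, dose =)` entries; arm 1 is
#'   the comparator (allopurinol), arm 2 the new treatment (febuxostat).
#' @param duration Trial duration in days.
#' @param inclusion_threshold Minimum baseline sUA (mg/dL); subjects qualify
#'   when baseline is strictly above the threshold.
#' @param scenario `"base_case"` or `"reduced"` parameter uncertainty.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(design_id, arms, duration = 182,
                         inclusion_threshold,
                         scenario = c("base_case", "reduced")) {
  scenario <- match.arg(scenario)
  check_scalar(duration, "duration", lower = 1)
  check_positive(inclusion_threshold, "inclusion_threshold")
  if (!is.list(arms) || length(arms) != 2L)
    abort_input("'arms' must be a list of exactly two regimens")
  for (a in arms) {
    if (is.null(a$drug) || is.null(a$dose)) abort_input("each arm needs 'drug' and 'dose'")
    check_positive(a$dose, "dose")
  }
  structure(list(design_id = as.character(design_id), arms = arms,
                 duration = as.integer(duration),
                 inclusion_threshold = inclusion_threshold,
                 scenario = scenario),
            class = "trial_design")
}

#' The six default trial designs
#'
#' Allopurinol 300/600 mg versus febuxostat 80/120 mg over 182 days, with
#' inclusion thresholds of 6 or 8 mg/dL: designs psi1-psi3 under base-case
#' input uncertainty, psi4-psi6 under reduced uncertainty.
#'
#' @return A named list of [trial_design()] objects.
#' @export
default_designs <- function() {
  grid <- list(
    list(id = "psi1", a = 300, f = 80, thr = 6, sc = "base_case"),
    list(id = "psi2", a = 300, f = 80, thr = 8, sc = "base_case"),
    list(id = "psi3", a = 600, f = 120, thr = 6, sc = "base_case"),
    list(id = "psi4", a = 300, f = 80, thr = 6, sc = "reduced"),
    list(id = "psi5", a = 300, f = 80, thr = 8, sc = "reduced"),
    list(id = "psi6", a = 600, f = 120, thr = 6, sc = "reduced"))
  out <- lapply(grid, function(g) {
    trial_design(g$id,
                 arms = list(list(drug = "allopurinol", dose = g$a),
                             list(drug = "febuxostat", dose = g$f)),
                 duration = 182, inclusion_threshold = g$thr,
                 scenario = g$sc)
  })
  names(out) <- vapply(out, `[[`, "", "design_id")
  out
}

#' Adherence and discontinuation parameters
#'
#' Treatment initiation is certain. While on treatment, each subject takes
#' each scheduled dose with a subject-specific probability drawn from a
#' logit-normal distribution whose population mean is
#' `implementation_mean` (the location parameter is solved numerically so the
#' mean is exact). Discontinuation follows a Weibull time-to-event with
#' `weibull_shape < 1`, i.e. a hazard that falls over time.
#'
#' @param initiation_prob Probability of starting treatment; fixed at 1.
#' @param implementation_mean Population mean per-dose taking probability.
#' @param implementation_dispersion SD of the subject-specific logit of the
#'   taking probability; 0 gives every subject the mean probability.
#' @param weibull_shape Weibull shape (dimensionless).
#' @param weibull_scale Weibull scale (days); `Inf` disables discontinuation.
#' @return An object of class `adherence_params` (carries the solved
#'   logit-scale location `mu_logit`).
#' @export
adherence_params <- function(initiation_prob = 1, implementation_mean = 0.9,
                             implementation_dispersion = 1,
                             weibull_shape = 0.5, weibull_scale = 7000) {
  if (!identical(as.numeric(initiation_prob), 1))
    abort_input("'initiation_prob' is fixed at 1: all patients initiate treatment")
  check_scalar(implementation_mean, "implementation_mean", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(implementation_dispersion, "implementation_dispersion", lower = 0)
  check_positive(weibull_shape, "weibull_shape")
  check_scalar(weibull_scale, "weibull_scale", lower = 0, strict_lower = TRUE,
               allow_inf = TRUE)
  mu <- if (implementation_dispersion == 0 || implementation_mean == 1) {
    qlogis(implementation_mean)  # perfect adherence degenerates to p = 1
  } else {
    logit_normal_location(implementation_mean, implementation_dispersion)
  }
  structure(list(initiation_prob = 1,
                 implementation_mean = implementation_mean,
                 implementation_dispersion = implementation_dispersion,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 mu_logit = mu),
            class = "adherence_params")
}

# Solve E[plogis(mu + sigma * Z)] = target for mu.
logit_normal_location <- function(target, sigma) {
  f <- function(mu) {
    integrate(function(z) plogis(mu + sigma * z) * dnorm(z),
              -Inf, Inf, rel.tol = 1e-10)$value - target
  }
  centre <- qlogis(target)
  uniroot(f, interval = centre + c(-1, 1) * (4 + sigma^2),
          tol = 1e-10)$root
}

#' Population attribute distributions
#'
#' The gout-population attributes sampled for each simulated cohort: baseline
#' sUA is lognormal; weight and age are normal, truncated to plausible
#' physiological ranges. Zero-variance settings collapse each attribute to a
#' point mass.
#'
#' @param baseline_sua `list(meanlog =, sdlog =)` for the lognormal baseline
#'   sUA (mg/dL).
#' @param weight,age `list(mean =, sd =, min =, max =)` truncated-normal
#'   specifications (kg; years).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(baseline_sua = list(meanlog = log(8.8), sdlog = 0.18),
                            weight = list(mean = 85, sd = 15, min = 40, max = 160),
                            age = list(mean = 55, sd = 11, min = 20, max = 90)) {
  check_scalar(baseline_sua$meanlog, "baseline_sua$meanlog")
  check_scalar(baseline_sua$sdlog, "baseline_sua$sdlog", lower = 0)
  for (nm in c("weight", "age")) {
    a <- get(nm)
    check_positive(a$mean, paste0(nm, "$mean"))
    check_scalar(a$sd, paste0(nm, "$sd"), lower = 0)
    if (a$min >= a$max) abort_input("'%s' truncation bounds are inverted", nm)
  }
  structure(list(baseline_sua = baseline_sua, weight = weight, age = age),
            class = "population_spec")
}

rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd == 0) return(rep(pmin(pmax(mean, min), max), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < min | x > max)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < min | x[bad] > max]
  }
  x
}

# Draws for one cohort under the ambient RNG state; order of draws is part of
# the reproducibility contract: baseline, weight, age, implementation logit,
# then one column of random effects per IIV parameter.
sample_population_raw <- function(pop, n, iiv = NULL, adherence = NULL) {
  baseline <- rlnorm(n, pop$baseline_sua$meanlog, pop$baseline_sua$sdlog)
  weight <- rtruncnorm(n, pop$weight$mean, pop$weight$sd,
                       pop$weight$min, pop$weight$max)
  age <- rtruncnorm(n, pop$age$mean, pop$age$sd, pop$age$min, pop$age$max)
  p_impl <- if (is.null(adherence)) {
    rep(1, n)
  } else if (adherence$implementation_dispersion == 0 ||
             adherence$implementation_mean == 1) {
    rep(adherence$implementation_mean, n)
  } else {
    plogis(rnorm(n, adherence$mu_logit, adherence$implementation_dispersion))
  }
  iiv <- iiv %||% numeric(0)
  eta <- matrix(0, n, length(iiv),
                dimnames = list(NULL, names(iiv)))
  for (j in seq_along(iiv)) eta[, j] <- rnorm(n, 0, iiv[[j]])
  structure(list(covariates = data.frame(baseline_sua = baseline,
                                         weight = weight, age = age),
                 p_impl = p_impl, eta = eta),
            class = "cohort")
}

#' Sample a trial cohort
#'
#' Draws `n` subjects from the population attribute distributions, together
#' with each subject's dose-implementation probability and log-scale random
#' effects for the parameters named in `iiv`.
#'
#' @param pop A [population_spec()].
#' @param n Number of subjects.
#' @param seed Integer seed; identical seeds reproduce the cohort exactly.
#' @param iiv Named numeric vector of between-subject log-normal SDs (e.g.
#'   `c(ka = 0.3, CL = 0.25)`).
#' @param adherence Optional [adherence_params()] used to draw the
#'   subject-specific implementation probabilities.
#' @return An object of class `cohort`: `covariates` data frame
#'   (`baseline_sua`, `weight`, `age`), `p_impl`, and an `eta` matrix.
#' @export
sample_population <- function(pop, n, seed, iiv = NULL, adherence = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  check_scalar(n, "n", lower = 1)
  withr::with_seed(as.integer(seed),
                   sample_population_raw(pop, as.integer(n), iiv, adherence))
}

cohort_size <- function(cohort) nrow(cohort$covariates)

subset_cohort <- function(cohort, keep) {
  structure(list(covariates = cohort$covariates[keep, , drop = FALSE],
                 p_impl = cohort$p_impl[keep],
                 eta = cohort$eta[keep, , drop = FALSE]),
            class = "cohort")
}

#' Apply the trial inclusion criterion
#'
#' Retains subjects whose baseline sUA is strictly above the threshold
#' ("minimum baseline" treated as exclusive, so a subject exactly at the
#' threshold is excluded). Order is preserved and the filter is idempotent.
#'
#' @param cohort A `cohort` (from [sample_population()]) or a data frame with
#'   a `baseline_sua` column.
#' @param threshold Minimum baseline sUA (mg/dL); 0 retains everyone.
#' @return The filtered cohort (warns, rather than errors, when empty).
#' @export
apply_inclusion <- function(cohort, threshold) {
  check_scalar(threshold, "threshold", lower = 0)
  if (inherits(cohort, "cohort")) {
    keep <- cohort$covariates$baseline_sua > threshold
    out <- subset_cohort(cohort, keep)
    n_left <- cohort_size(out)
  } else if (is.data.frame(cohort)) {
    out <- cohort[cohort$baseline_sua > threshold, , drop = FALSE]
    n_left <- nrow(out)
  } else {
    abort_input("'cohort' must be a cohort object or data frame")
  }
  if (n_left == 0L) warning("inclusion filter removed all subjects")
  out
}

# Sample post-inclusion cohorts of exactly n subjects by rejection: attribute
# draws are cheap, so batches are drawn until n subjects qualify.
sample_included_cohort <- function(pop, n, threshold, seed, iiv, adherence,
                                   max_batches = 200L) {
  withr::with_seed(as.integer(seed), {
    pieces <- list()
    got <- 0L
    batch <- max(n, 32L)
    for (b in seq_len(max_batches)) {
      raw <- sample_population_raw(pop, batch, iiv, adherence)
      keep <- raw$covariates$baseline_sua > threshold
      if (any(keep)) {
        pieces[[length(pieces) + 1L]] <- subset_cohort(raw, keep)
        got <- got + sum(keep)
      }
      if (got >= n) break
    }
    if (got < n)
      abort_input("could not assemble %d subjects above threshold %g", n, threshold)
    all <- structure(list(
      covariates = do.call(rbind, lapply(pieces, function(p) p$covariates)),
      p_impl = unlist(lapply(pieces, `[[`, "p_impl")),
      eta = do.call(rbind, lapply(pieces, `[[`, "eta"))), class = "cohort")
    subset_cohort(all, seq_len(n))
  })
}

#' Sample a dosing history under imperfect adherence
#'
#' The discontinuation day is drawn from the discrete-day Weibull
#' survival `S(t) = exp(-(t / scale)^shape)` (a subject is still on treatment
#' at day `t` with probability `S(t)`); doses before that day are taken as
#' independent Bernoulli trials with the subject's implementation
#' probability, independent of whether any previous dose was taken.
#'
#' @param adh An [adherence_params()].
#' @param p_impl Subject-specific per-dose taking probability.
#' @param dose Dose per administration (mg).
#' @param duration Trial duration (days).
#' @param seed Integer seed.
#' @return A [dosing_history()]; `dropout_day` is `NA` for completers.
#' @export
sample_dosing_history <- function(adh, p_impl, dose, duration, seed) {
  stopifnot(inherits(adh, "adherence_params"))
  check_scalar(p_impl, "p_impl", lower = 0, upper = 1)
  check_scalar(duration, "duration", lower = 1)
  withr::with_seed(as.integer(seed), {
    u <- runif(1)
    x <- adh$weibull_scale * (-log(u))^(1 / adh$weibull_shape)
    dropout <- if (is.finite(x) && x <= duration) max(1, ceiling(x)) else NA
    taken <- rbinom(duration, 1L, p_impl)
    dosing_history(dose, duration, taken, dropout)
  })
}

# Vectorized dosing draws for a whole arm under one seed: first the n dropout
# uniforms, then the duration x n implementation Bernoullis.
sample_dosing_matrix <- function(adh, p_impl, duration, seed) {
  n <- length(p_impl)
  withr::with_seed(as.integer(seed), {
    u <- runif(n)
    x <- adh$weibull_scale * (-log(u))^(1 / adh$weibull_shape)
    dropout <- ifelse(is.finite(x) & x <= duration, pmax(1, ceiling(x)), NA)
    taken <- matrix(rbinom(n * duration, 1L, rep(p_impl, each = duration)),
                    nrow = duration, ncol = n)
    day <- matrix(seq_len(duration), duration, n)
    cut <- matrix(ifelse(is.na(dropout), Inf, dropout), duration, n, byrow = TRUE)
    taken[day >= cut] <- 0L
    list(taken = taken, dropout_day = dropout)
  })
}

#' Simulate one arm of a trial
#'
#' Individualizes the population PK/PD parameters for every subject,
#' calibrates each subject's production rate to their baseline sUA, draws
#' dosing histories, and integrates the PK/PD model to the final-day trough.
#' Subjects who discontinue revert to their baseline sUA exactly, so they are
#' non-responders unless their baseline was already below 6 mg/dL.
#'
#' @param design A [trial_design()].
#' @param arm Arm index (1 = comparator, 2 = new treatment).
#' @param cohort A post-inclusion `cohort`.
#' @param pk,pd Population [pk_params()] / [pd_params()] for the arm's drug.
#' @param adh An [adherence_params()].
#' @param seed Integer seed for the arm's dosing draws.
#' @param cmod A [covariate_model()].
#' @return An `arm_result` data frame: covariates, `dropout_day`,
#'   `final_sua` (mg/dL) and `responder` (`final_sua < 6`).
#' @export
simulate_arm <- function(design, arm, cohort, pk, pd, adh, seed,
                         cmod = covariate_model()) {
  stopifnot(inherits(design, "trial_design"), inherits(cohort, "cohort"),
            inherits(pk, "pk_params"), inherits(pd, "pd_params"),
            inherits(adh, "adherence_params"))
  if (!arm %in% c(1L, 2L)) abort_input("'arm' must be 1 or 2")
  n <- cohort_size(cohort)
  if (n == 0L) abort_input("empty cohort")
  dose <- design$arms[[arm]]$dose
  duration <- design$duration
  cov <- cohort$covariates

  ind <- individualize_cohort(pk, pd, cov, cohort$eta, cmod)
  dosing <- sample_dosing_matrix(adh, cohort$p_impl, duration, seed)
  dropped <- !is.na(dosing$dropout_day)

  final <- cov$baseline_sua  # reversion rule: dropouts end at baseline
  run <- which(!dropped)
  if (length(run)) {
    mac <- with(ind, pk_macro_vec(pk$model, ka[run], CL[run], V1[run],
                                  if (pk$model == "two_compartment") Q[run],
                                  if (pk$model == "two_compartment") V2[run],
                                  pk$F))
    tr <- cohort_troughs(mac$lambda, mac$coef, mac$nexp,
                         rep(dose, length(run)),
                         dosing$taken[, run, drop = FALSE],
                         ind$kin[run], ind$k1[run], ind$k2[run],
                         ind$e_hx[run], ind$e_x[run], ind$e_ua[run],
                         ind$V_ua[run], ind$Imax[run], ind$IC50[run],
                         ind$Emax_x[run], ind$EC50_x[run],
                         duration, 20L)
    final[run] <- tr[duration, ]
  }
  out <- data.frame(baseline_sua = cov$baseline_sua, weight = cov$weight,
                    age = cov$age, dropout_day = dosing$dropout_day,
                    final_sua = final, responder = final < 6)
  attr(out, "design_id") <- design$design_id
  attr(out, "arm") <- arm
  attr(out, "drug") <- design$arms[[arm]]$drug
  class(out) <- c("arm_result", "data.frame")
  out
}

# Vectorized individualization + baseline calibration for a whole cohort.
# Mirrors individualize_params()/calibrate_baseline() but returns flat
# per-subject parameter vectors for the compiled solver.
individualize_cohort <- function(pk, pd, cov, eta, cmod) {
  n <- nrow(cov)
  w_cl <- (cov$weight / cmod$ref_weight)^cmod$weight_exp_cl
  w_v <- (cov$weight / cmod$ref_weight)^cmod$weight_exp_v
  a_renal <- exp(cmod$age_slope_renal * (cov$age - cmod$ref_age))
  ex_eta <- function(nm) {
    if (!is.null(colnames(eta)) && nm %in% colnames(eta)) exp(eta[, nm]) else rep(1, n)
  }
  ka <- pk$ka * ex_eta("ka")
  CL <- pk$CL * w_cl * ex_eta("CL")
  V1 <- pk$V1 * w_v * ex_eta("V1")
  Q <- V2 <- NULL
  if (pk$model == "two_compartment") {
    Q <- pk$Q * w_cl * ex_eta("Q")
    V2 <- pk$V2 * w_v * ex_eta("V2")
  }
  k1 <- rep(pd$k_hx_x, n)
  k2 <- rep(pd$k_x_ua, n)
  e_hx <- pd$CLr_hx * w_cl * a_renal / (pd$V_hx * w_v)
  e_x <- pd$CLr_x * w_cl * a_renal / (pd$V_x * w_v)
  e_ua <- pd$CLr_ua * w_cl * a_renal / (pd$V_ua * w_v)
  V_ua <- pd$V_ua * w_v
  IC50 <- pd$IC50 * ex_eta("IC50")
  Imax <- rep(pd$Imax, n)
  Emax_x <- rep(pd$Emax_x, n)
  EC50_x <- pd$EC50_x * ex_eta("EC50_x")
  # linear chain: kin scales one-to-one with the target baseline amount
  f1 <- k1 / (k1 + e_hx)
  f2 <- k2 / (k2 + e_x)
  kin <- cov$baseline_sua * 10 * V_ua * e_ua / (f1 * f2)
  list(ka = ka, CL = CL, V1 = V1, Q = Q, V2 = V2, kin = kin, k1 = k1,
       k2 = k2, e_hx = e_hx, e_x = e_x, e_ua = e_ua, V_ua = V_ua,
       Imax = Imax, IC50 = IC50, Emax_x = Emax_x, EC50_x = EC50_x)
}

#' Response rate of a simulated arm
#'
#' The proportion of subjects with final trough sUA strictly below 6 mg/dL;
#' a subject ending exactly at 6 mg/dL is a non-responder.
#'
#' @param result An `arm_result` from [simulate_arm()].
#' @return Proportion in `[0, 1]`.
#' @export
response_rate <- function(result) {
  if (!is.data.frame(result) || nrow(result) == 0L)
    abort_input("'result' must be a non-empty arm result")
  stopifnot(identical(result$responder, result$final_sua < 6))
  mean(result$responder)
}

#' Write per-subject arm results to CSV
#'
#' @param result An `arm_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arm_result_csv <- function(result, path) {
  stopifnot(inherits(result, "arm_result"))
  write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
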