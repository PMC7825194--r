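#' Population pharmacokinetic parameters
#'
#' Linear disposition with first-order absorption. Allopurinol-like drugs use
#' a one-compartment model; febuxostat-like drugs a two-compartment model.
#' All rates are per day, volumes in litres, clearances in litres/day, so that
#' an oral dose in mg yields concentrations in mg/L.
#'
#' @param model `"one_compartment"` or `"two_compartment"`.
#' @param ka First-order absorption rate constant (1/day).
#' @param CL Apparent clearance (L/day).
#' @param V1 Central volume of distribution (L).
#' @param Q Inter-compartmental clearance (L/day); two-compartment only.
#' @param V2 Peripheral volume (L); two-compartment only.
#' @param F Oral bioavailability fraction in (0, 1].
#' @return An object of class `pk_params`.
#' @export
#' @examples
#' pk_params("one_compartment", ka = 15, CL = 30, V1 = 60, F = 0.8)
pk_params <- function(model = c("one_compartment", "two_compartment"),
                      ka, CL, V1, Q = NULL, V2 = NULL, F = 1) {
  model <- match.arg(model)
  check_positive(ka, "ka")
  check_positive(CL, "CL")
  check_positive(V1, "V1")
  check_scalar(F, "F", lower = 0, upper = 1, strict_lower = TRUE)
  if (model == "one_compartment") {
    if (!is.null(Q) || !is.null(V2))
      abort_input("'Q' and 'V2' must be absent for a one-compartment model")
  } else {
    check_positive(Q, "Q")
    check_positive(V2, "V2")
  }
  structure(list(model = model, ka = ka, CL = CL, V1 = V1,
                 Q = Q, V2 = V2, F = F),
            class = "pk_params")
}

#' Pharmacodynamic parameters of the uric acid turnover chain
#'
#' A three-state chain of drug-free purine turnover: hypoxanthine is produced
#' at a constant rate `kin`, converted to xanthine and then to uric acid by
#' xanthine oxidase, with parallel first-order renal elimination of all three
#' species. The drug inhibits both oxidase steps through a shared Emax-type
#' term `I(C) = Imax * C / (IC50 + C)`; febuxostat-like drugs additionally
#' stimulate renal excretion of xanthine through
#' `S(C) = Emax_x * C / (EC50_x + C)`. States are amounts (mg); serum uric
#' acid is reported in mg/dL (`amount / V_ua / 10`).
#'
#' @param kin Zero-order precursor production rate (mg/day).
#' @param k_hx_x,k_x_ua Oxidase-mediated conversion rate constants (1/day).
#' @param CLr_hx,CLr_x,CLr_ua Renal clearances (L/day).
#' @param V_hx,V_x,V_ua Distribution volumes (L).
#' @param Imax Maximal fractional inhibition of both oxidase steps, in
#'   `[0, 1]`.
#' @param IC50 Concentration of half-maximal inhibition (mg/L).
#' @param Emax_x Maximal fractional stimulation of xanthine renal excretion
#'   (dimensionless, `>= 0`; 0 disables the effect).
#' @param EC50_x Concentration of half-maximal stimulation (mg/L).
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(kin, k_hx_x, k_x_ua, CLr_hx, CLr_x, CLr_ua,
                      V_hx, V_x, V_ua, Imax, IC50,
                      Emax_x = 0, EC50_x = 1) {
  for (nm in c("kin", "k_hx_x", "k_x_ua", "CLr_hx", "CLr_x", "CLr_ua",
               "V_hx", "V_x", "V_ua", "IC50", "EC50_x")) {
    check_positive(get(nm), nm)
  }
  check_scalar(Imax, "Imax", lower = 0, upper = 1)
  check_scalar(Emax_x, "Emax_x", lower = 0)
  structure(list(kin = kin, k_hx_x = k_hx_x, k_x_ua = k_x_ua,
                 CLr_hx = CLr_hx, CLr_x = CLr_x, CLr_ua = CLr_ua,
                 V_hx = V_hx, V_x = V_x, V_ua = V_ua,
                 Imax = Imax, IC50 = IC50,
                 Emax_x = Emax_x, EC50_x = EC50_x),
            class = "pd_params")
}

#' Subject covariates
#'
#' Baseline serum uric acid, body weight and age: the three attributes used
#' as covariates in the PK/PD model.
#'
#' @param baseline_sua Baseline serum uric acid (mg/dL).
#' @param weight Body weight (kg).
#' @param age Age (years).
#' @return An object of class `subject_covariates`.
#' @export
subject_covariates <- function(baseline_sua, weight, age) {
  check_positive(baseline_sua, "baseline_sua")
  check_positive(weight, "weight")
  check_positive(age, "age")
  structure(list(baseline_sua = baseline_sua, weight = weight, age = age),
            class = "subject_covariates")
}

#' Individual dosing history
#'
#' Once-daily dosing over a trial of `duration` days. `taken[i]` indicates
#' whether the dose scheduled at the start of day `i` (time `i - 1` days) was
#' taken. A subject who discontinues on `dropout_day = d` takes no dose from
#' day `d` onwards; the constructor enforces this by zeroing those entries.
#'
#' @param dose_amount Dose per administration (mg).
#' @param duration Trial duration (days).
#' @param taken Binary vector of length `duration`.
#' @param dropout_day Day index of discontinuation (1-based), or `NA` if the
#'   subject completes the trial.
#' @return An object of class `dosing_history`.
#' @export
dosing_history <- function(dose_amount, duration, taken = rep(1L, duration),
                           dropout_day = NA) {
  check_scalar(dose_amount, "dose_amount", lower = 0)
  check_scalar(duration, "duration", lower = 1)
  duration <- as.integer(duration)
  if (length(taken) != duration)
    abort_input("'taken' must have exactly %d entries", duration)
  check_flag_vector(taken, "taken")
  taken <- as.integer(taken)
  if (!is.na(dropout_day)) {
    check_scalar(dropout_day, "dropout_day", lower = 1, upper = duration)
    dropout_day <- as.integer(dropout_day)
    taken[dropout_day:duration] <- 0L
  }
  structure(list(dose_amount = dose_amount, duration = duration,
                 taken = taken, dropout_day = dropout_day),
            class = "dosing_history")
}

#' Covariate model for parameter individualization
#'
#' Conventional pharmacometric covariate structure: allometric weight scaling
#' (default exponent 0.75 on clearances, 1 on volumes) and a log-linear age
#' effect on renal clearances.
#'
#' @param ref_weight Reference body weight (kg).
#' @param ref_age Reference age (years).
#' @param weight_exp_cl Allometric exponent applied to clearances.
#' @param weight_exp_v Allometric exponent applied to volumes.
#' @param age_slope_renal Log-linear slope (per year) applied to renal
#'   clearances: multiplier `exp(age_slope_renal * (age - ref_age))`.
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(ref_weight = 70, ref_age = 60,
                            weight_exp_cl = 0.75, weight_exp_v = 1,
                            age_slope_renal = -0.01) {
  check_positive(ref_weight, "ref_weight")
  check_positive(ref_age, "ref_age")
  check_scalar(weight_exp_cl, "weight_exp_cl")
  check_scalar(weight_exp_v, "weight_exp_v")
  check_scalar(age_slope_renal, "age_slope_renal")
  structure(list(ref_weight = ref_weight, ref_age = ref_age,
                 weight_exp_cl = weight_exp_cl, weight_exp_v = weight_exp_v,
                 age_slope_renal = age_slope_renal),
            class = "covariate_model")
}

apply_eta <- function(params, eta) {
  if (is.null(eta) || length(eta) == 0) return(params)
  if (is.null(names(eta)) || any(names(eta) == ""))
    abort_input("random effects must be a named numeric vector")
  if (any(!is.finite(eta))) abort_input("random effects must be finite")
  for (nm in names(eta)) {
    if (!is.null(params[[nm]])) params[[nm]] <- params[[nm]] * exp(eta[[nm]])
  }
  params
}

#' Individualize population PK/PD parameters
#'
#' Each individual parameter is the population value multiplied by its
#' covariate multiplier and a lognormal random-effect factor `exp(eta)`.
#' Weight scales clearances (`CL`, `Q`, `CLr_*`) allometrically and volumes
#' (`V1`, `V2`, `V_*`) proportionally; age acts log-linearly on the renal
#' clearances only. Random effects are supplied on the log scale as named
#' vectors (e.g. `c(ka = 0.1)`); names not present in the parameter set are
#' ignored.
#'
#' @param pk A [pk_params()] object (population values).
#' @param pd A [pd_params()] object (population values).
#' @param cov A [subject_covariates()] object.
#' @param eta_pk,eta_pd Named numeric vectors of log-scale random effects.
#' @param cmod A [covariate_model()].
#' @return `list(pk = , pd = )` with individualized, validated parameters.
#' @export
individualize_params <- function(pk, pd, cov, eta_pk = NULL, eta_pd = NULL,
                                 cmod = covariate_model()) {
  stopifnot(inherits(pk, "pk_params"), inherits(pd, "pd_params"),
            inherits(cmod, "covariate_model"))
  if (!inherits(cov, "subject_covariates"))
    cov <- do.call(subject_covariates, as.list(cov)[c("baseline_sua", "weight", "age")])
  w_cl <- (cov$weight / cmod$ref_weight)^cmod$weight_exp_cl
  w_v <- (cov$weight / cmod$ref_weight)^cmod$weight_exp_v
  a_renal <- exp(cmod$age_slope_renal * (cov$age - cmod$ref_age))

  pk_i <- unclass(pk)
  pk_i$CL <- pk_i$CL * w_cl
  pk_i$V1 <- pk_i$V1 * w_v
  if (pk$model == "two_compartment") {
    pk_i$Q <- pk_i$Q * w_cl
    pk_i$V2 <- pk_i$V2 * w_v
  }
  pk_i <- apply_eta(pk_i, eta_pk)

  pd_i <- unclass(pd)
  for (nm in c("CLr_hx", "CLr_x", "CLr_ua")) {
    pd_i[[nm]] <- pd_i[[nm]] * w_cl * a_renal
  }
  for (nm in c("V_hx", "V_x", "V_ua")) pd_i[[nm]] <- pd_i[[nm]] * w_v
  pd_i <- apply_eta(pd_i, eta_pd)

  list(pk = do.call(pk_params, pk_i[c("model", "ka", "CL", "V1", "Q", "V2", "F")]),
       pd = do.call(pd_params, pd_i[setdiff(names(pd_i), NULL)]))
}

#' Analytic steady-state serum uric acid under a constant drug concentration
#'
#' Closed form of the three-state turnover chain under constant fractional
#' inhibition `I(C)` of both oxidase steps and stimulation `S(C)` of xanthine
#' renal excretion. Used both to initialise simulations at the drug-free
#' baseline and as an analytic oracle for the numerical integrator.
#'
#' @param pd A [pd_params()] object.
#' @param conc Constant drug concentration (mg/L), `>= 0`.
#' @return Steady-state serum uric acid (mg/dL).
#' @export
#' @examples
#' pd <- pd_params(kin = 700, k_hx_x = 5, k_x_ua = 5, CLr_hx = 20,
#'                 CLr_x = 20, CLr_ua = 8.4, V_hx = 40, V_x = 40, V_ua = 12,
#'                 Imax = 0.9, IC50 = 1.7)
#' steady_state_urate(pd, 0)
steady_state_urate <- function(pd, conc) {
  stopifnot(inherits(pd, "pd_params"))
  check_scalar(conc, "conc", lower = 0)
  ss_amounts(pd, conc)[3] / pd$V_ua / 10
}

# Steady-state amounts (mg) of the chain at constant concentration C.
ss_amounts <- function(pd, C) {
  I <- pd$Imax * C / (pd$IC50 + C)
  S <- if (pd$Emax_x > 0) pd$Emax_x * C / (pd$EC50_x + C) else 0
  k1 <- pd$k_hx_x * (1 - I)
  k2 <- pd$k_x_ua * (1 - I)
  e_hx <- pd$CLr_hx / pd$V_hx
  e_x <- pd$CLr_x / pd$V_x * (1 + S)
  e_ua <- pd$CLr_ua / pd$V_ua
  a_hx <- pd$kin / (k1 + e_hx)
  a_x <- k1 * a_hx / (k2 + e_x)
  a_ua <- k2 * a_x / e_ua
  c(a_hx, a_x, a_ua)
}

#' Calibrate the production rate to a subject's baseline sUA
#'
#' Rescales `kin` so the drug-free steady state of the chain equals the
#' observed baseline. The chain is linear in `kin`, so the calibration is a
#' single exact rescaling.
#'
#' @param pd A [pd_params()] object.
#' @param baseline_sua Target drug-free steady-state sUA (mg/dL).
#' @return The calibrated [pd_params()] object.
#' @export
calibrate_baseline <- function(pd, baseline_sua) {
  stopifnot(inherits(pd, "pd_params"))
  check_positive(baseline_sua, "baseline_sua")
  current <- steady_state_urate(pd, 0)
  kin_new <- pd$kin * baseline_sua / current
  if (!is.finite(kin_new) || kin_new <= 0)
    abort_input("calibration infeasible: no positive 'kin' attains baseline %g",
                baseline_sua)
  pd$kin <- kin_new
  achieved <- steady_state_urate(pd, 0)
  if (abs(achieved - baseline_sua) > 1e-3 * baseline_sua)
    abort_input("calibration failed to reach baseline within 0.1%%")
  pd
}
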