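# Configuration: a plain nested list (YAML-serializable) holding every input
# of the four-stage framework. default_config() doubles as the fixture
# generator: the drug, population and economic blocks are synthetic defaults
# chosen for pharmacological plausibility and are fully config-driven, so
# estimated parameter sets can be dropped in without code changes.

#' Generate the default run configuration and fixture parameter set
#'
#' Emits a complete, validated configuration: the six default trial designs
#' (182-day, allopurinol 300/600 mg vs febuxostat 80/120 mg, inclusion
#' thresholds 6/8 mg/dL, base-case and reduced uncertainty scenarios),
#' synthetic population PK/PD parameter blocks for both drugs, gout
#' population attribute distributions, adherence/discontinuation defaults,
#' the Markov cost-effectiveness inputs and the ROI/market inputs. Replicate
#' counts default to the scaled-down setting (R = 200 replicates, N = 200
#' subjects per arm); the full-fidelity counts (R = 10000, N = 1000) are
#' carried alongside and selected with `fidelity = "full"` in
#' [run_pipeline()].
#'
#' @param seed Master seed stored in the configuration.
#' @return A named list; see [validate_config()].
#' @export
default_config <- function(seed = 1L) {
  list(
    master_seed = as.integer(seed),
    run = list(
      replicates = 200L, cohort_size = 200L,
      replicates_full = 10000L, cohort_size_full = 1000L,
      preposterior_replicates = 500L,
      sample_size_grid = c(50L, 100L, 150L, 200L, 300L, 400L, 500L, 600L),
      lambda = 20000, point_estimate = "mean", workers = 1L),
    designs = lapply(unname(default_designs()), unclass),
    drugs = list(
      allopurinol = list(
        pk = list(model = "one_compartment", ka = 15, CL = 30, V1 = 60,
                  F = 0.8),
        effect = list(Imax = 0.9, IC50 = 1.7, Emax_x = 0, EC50_x = 1),
        iiv = list(ka = 0.3, CL = 0.25, V1 = 0.2, IC50 = 0.3)),
      febuxostat = list(
        pk = list(model = "two_compartment", ka = 20, CL = 250, V1 = 40,
                  Q = 150, V2 = 60, F = 0.85),
        effect = list(Imax = 0.95, IC50 = 0.03, Emax_x = 1, EC50_x = 0.1),
        iiv = list(ka = 0.3, CL = 0.25, V1 = 0.2, Q = 0.2, V2 = 0.2,
                   IC50 = 0.3))),
    pd_system = list(kin = 700, k_hx_x = 5, k_x_ua = 5, CLr_hx = 20,
                     CLr_x = 20, CLr_ua = 8.4, V_hx = 40, V_x = 40,
                     V_ua = 12),
    population = list(
      baseline_sua = list(meanlog = log(8.8), sdlog = 0.18),
      weight = list(mean = 85, sd = 15, min = 40, max = 160),
      age = list(mean = 55, sd = 11, min = 20, max = 90)),
    adherence = list(initiation_prob = 1, implementation_mean = 0.9,
                     implementation_dispersion = 1,
                     weibull_shape = 0.5, weibull_scale = 7000),
    covariates = list(ref_weight = 70, ref_age = 60, weight_exp_cl = 0.75,
                      weight_exp_v = 1, age_slope_renal = -0.01),
    uncertainty = list(
      base_case = list(
        cv_pk = list(ka = 0.2, CL = 0.2, V1 = 0.2, Q = 0.2, V2 = 0.2),
        cv_effect = list(IC50 = 0.3, Emax_x = 0.2, EC50_x = 0.2),
        cv_system = list(k_hx_x = 0.15, k_x_ua = 0.15, CLr_hx = 0.15,
                         CLr_x = 0.15, CLr_ua = 0.15, V_hx = 0.15,
                         V_x = 0.15, V_ua = 0.15)),
      reduced = list(
        cv_pk = list(ka = 0.2 / 3, CL = 0.2 / 3, V1 = 0.2 / 3,
                     Q = 0.2 / 3, V2 = 0.2 / 3),
        cv_effect = list(IC50 = 0.1, Emax_x = 0.2 / 3, EC50_x = 0.2 / 3),
        cv_system = list(k_hx_x = 0.05, k_x_ua = 0.05, CLr_hx = 0.05,
                         CLr_x = 0.05, CLr_ua = 0.05, V_hx = 0.05,
                         V_x = 0.05, V_ua = 0.05))),
    econ = list(cycle_years = 0.25, horizon_years = 50,
                discount_annual = 0.035,
                flare_rate_annual = c(0.35, 1.2, 2.5), flare_cost = 250,
                utility = c(0.87, 0.82, 0.76), flare_disutility = 0.012,
                care_cost_annual = c(150, 200, 300), mortality_annual = 0.02,
                nonresponder_split = c(0.5, 0.5),
                dropout_shape = 0.5, dropout_scale_days = 7000,
                comparator_price_annual = 30, days_per_year = 365.25),
    roi = list(
      inputs = list(trial_fixed_cost = 5e6, trial_variable_cost = 2e4,
                    production_marketing = 10, minimum_price = 70),
      market = list(annual_incidence = 15000, horizon_years = 10,
                    uptake = 1, halving_threshold = 8))
  )
}

# Leaf fields stored as numeric vectors; YAML reads them back as lists, so
# both representations are normalized to vectors before use or comparison.
.vector_leaves <- list(
  c("run", "sample_size_grid"),
  c("econ", "flare_rate_annual"), c("econ", "utility"),
  c("econ", "care_cost_annual"), c("econ", "nonresponder_split"))

normalize_config <- function(config) {
  for (path in .vector_leaves) {
    v <- config[[path]]
    if (!is.null(v)) config[[path]] <- unname(unlist(v))
  }
  for (dn in names(config$drugs)) {
    config$drugs[[dn]]$iiv <- as.list(config$drugs[[dn]]$iiv)
  }
  for (sc in names(config$uncertainty)) {
    config$uncertainty[[sc]] <- lapply(config$uncertainty[[sc]], as.list)
  }
  config$master_seed <- as.integer(config$master_seed)
  config
}

# Build typed model objects from a configuration, validating every block.
config_objects <- function(config) {
  config <- normalize_config(config)
  designs <- lapply(config$designs, function(d) {
    trial_design(d$design_id, d$arms, d$duration, d$inclusion_threshold,
                 d$scenario)
  })
  names(designs) <- vapply(designs, `[[`, "", "design_id")
  params <- list(system = config$pd_system,
                 drugs = lapply(config$drugs, function(d) {
                   list(pk = d$pk, effect = d$effect, iiv = unlist(d$iiv))
                 }))
  for (dn in names(params$drugs)) assemble_arm_params(params, dn)  # validates
  pop <- do.call(population_spec, config$population)
  adh <- do.call(adherence_params, config$adherence)
  cmod <- do.call(covariate_model, config$covariates)
  unc <- lapply(setNames(nm = c("base_case", "reduced")), function(sc) {
    u <- config$uncertainty[[sc]]
    uncertainty_spec(u$cv_pk, u$cv_effect, u$cv_system, scenario = sc)
  })
  cv_at <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  for (block in c("cv_pk", "cv_effect", "cv_system")) {
    for (nm in names(unc$base_case[[block]])) {
      if (cv_at(unc$reduced[[block]], nm) > cv_at(unc$base_case[[block]], nm))
        abort_input("reduced-scenario CVs must not exceed base-case CVs ('%s')", nm)
    }
  }
  econ <- do.call(markov_spec, config$econ)
  roi_in <- do.call(roi_inputs, config$roi$inputs)
  market <- do.call(market_model, config$roi$market)
  run <- config$run
  if (run$replicates > run$replicates_full ||
      run$cohort_size > run$cohort_size_full)
    abort_input("scaled replicate counts must not exceed the full-fidelity counts")
  list(config = config, designs = designs, params = params, pop = pop,
       adh = adh, cmod = cmod, unc = unc, econ = econ, roi = roi_in,
       market = market, run = run)
}

#' Validate a run configuration
#'
#' Rebuilds every typed model object from the configuration, running all
#' block validators; errors describe the offending field.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The normalized configuration, invisibly.
#' @export
validate_config <- function(config) {
  if (is.null(config$master_seed)) abort_input("configuration must carry 'master_seed'")
  invisible(config_objects(config)$config)
}

#' Read / write configurations as YAML
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config` returns the normalized, validated configuration;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config, precision = 15L), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config <- normalize_config(yaml::yaml.load_file(path))
  validate_config(config)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical JSON serialization; stamped into every output
#' so results are traceable to their exact inputs. Numeric fields enter the
#' digest at 10 significant digits, so a configuration keeps its hash across
#' a YAML round trip.
#'
#' @param config A configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  config <- normalize_config(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10), tmp)
  unname(tools::md5sum(tmp))
}
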