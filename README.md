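# ctsroi

Model-based clinical trial simulation, Bayesian updating, cost-effectiveness
pricing and return-on-investment optimal sample size — in one reproducible
pipeline, for a two-arm urate-lowering trial (febuxostat vs allopurinol in
gout).

## Who this is for

Pharmacometricians and health-economic modellers who want to choose a
confirmatory trial design decision-theoretically rather than by type-I/II
error thresholds: the worth of a larger trial is measured by its effect on
the sponsor's expected return on investment, with drug price contingent on
the trial outcome through a payer's cost-effectiveness rule.

## The model chain

1. **Clinical trial simulation.** Linked PK/PD models (one-compartment
   allopurinol, two-compartment febuxostat; an indirect-response chain of
   uric acid turnover with both xanthine-oxidase steps inhibited by
   `I(C) = Imax·C/(IC50+C)`) plus a trial-execution model: inclusion at
   baseline sUA above a threshold, per-dose Bernoulli implementation with
   population mean 0.9, Weibull discontinuation with falling hazard, and
   exact reversion of dropouts to baseline. The endpoint is the proportion
   of subjects with final-day trough sUA < 6 mg/dL. Replication with
   constant-CV lognormal resampling of the population parameters turns the
   endpoint into a distribution θ per arm.
2. **Bayesian updating.** Moment matching `ν = m(1−m)/s² − 1`, `α = mν`,
   `β = (1−m)ν` converts each simulated distribution into a Beta prior;
   proposed data `m ~ Bin(n, θ)` update it conjugately to
   `Beta(α + m, β + n − m)` on the per-arm grid
   n ∈ {50, 100, 150, 200, 300, 400, 500, 600}.
3. **Pricing.** A Markov cohort model (sUA bands < 6 / 6–8 / > 8 + death,
   3-month cycles, 50-year horizon, 3.5% discounting) maps response to
   QALYs `Q` and costs `C`; setting the incremental net monetary benefit
   `λ(Q₂−Q₁) − (C₂−C₁)` to zero gives the maximum reimbursement price
   `P₂ = [C₁ − C̄₂ + λ(Q₂−Q₁)]/t₂`.
4. **ROI.** `ROI = (P₂ − C_PM)·t₂·S(H) − C_trial` if `P₂ ≥ P_min`, else 0
   (development terminates). The expectation over the prior predictive,
   maximized over n, is the recommended sample size.

Six prebuilt designs vary dose (300/80, 600/120 mg), inclusion threshold
(6 or 8 mg/dL) and input-uncertainty scenario (base case vs reduced). All
parameter sets are configuration values generated by `default_config()` —
synthetic but pharmacologically shaped — so estimated blocks can be dropped
in without code changes. See the methods vignette
(`vignettes/trial-design-roi.Rmd`) for model details and design choices.

## Worked example

Fit Beta priors from simulated response summaries (mean, SD), update with
proposed trial data, and optimize the sample size:

```r
library(ctsroi)

prior_allo  <- fit_beta_moments(0.36, 0.106)   # comparator arm
prior_febux <- fit_beta_moments(0.67, 0.063)   # new treatment arm
prior_allo
#> Beta(alpha = 7.02199, beta = 12.4835): mean 0.3600, sd 0.1060

posterior_update(prior_allo, m = 36, n = 100)
#> Beta(alpha = 43.022, beta = 76.4835): mean 0.3600, sd 0.0437

roi <- expected_roi(prior_allo, prior_febux,
                    n_grid = c(50, 100, 150, 200, 300, 400, 500, 600),
                    R = 2000, seed = 1, econ = markov_spec(),
                    roi = roi_inputs(), market = market_model(),
                    inclusion_threshold = 6)
roi
#>     n expected_roi p_termination optimal
#> 1  50    967929026        0.0025    TRUE
#> 2 100    964363436        0.0055   FALSE
#> 3 150    961793922        0.0065   FALSE
#> ...
```

Reading the output: at each per-arm size `n`, `expected_roi` is the mean ROI
(£) over 2,000 prior-predictive trial outcomes — revenue at the payer's
maximum reimbursement price over ten years of sales, net of production and
trial costs — and `p_termination` is the probability that the priced
outcome falls below the sponsor's £70/year minimum and development stops.
Under these priors the evidence is already strong, so extra subjects buy
little pricing information and the cheapest trial wins (`optimal` flags
n = 50).

The full four-stage pipeline, with CSV/JSON outputs, caching and logging:

```r
cfg <- default_config(seed = 42)
bundle <- run_pipeline(cfg, stages = "optimize-n", outdir = "results")
bundle$roi           # expected ROI per design and n
```

A thin CLI wrapper with the same stages lives at `inst/scripts/ctsroi`
(`ctsroi generate-config`, `simulate-trial`, `fit-prior`,
`evaluate-design`, `optimize-n`).

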