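---
title: "Model-based trial simulation and ROI-optimal sample size for urate-lowering therapies"
author: "ctsroi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based trial simulation and ROI-optimal sample size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsroi)
```

# The decision problem

A sponsor planning a confirmatory two-arm trial of a urate-lowering therapy
(febuxostat, versus the standard of care allopurinol) must pick a design —
doses, inclusion criterion, duration — and a per-arm sample size. `ctsroi`
frames that choice decision-theoretically: the value of enrolling more
patients is that the resulting evidence changes the price a cost-conscious
payer will reimburse, and hence the sponsor's revenue; the cost is the
marginal trial cost. The package chains four models so that uncertainty in
drug pharmacology propagates all the way to an expected return on investment
(ROI) per design and sample size:

1. **Clinical trial simulation (CTS).** A population PK/PD model plus a
   trial-execution model (inclusion criterion, imperfect dose-taking,
   discontinuation) simulates the trial endpoint — the proportion of
   subjects with trough serum uric acid (sUA) below 6 mg/dL on the final
   day — for each arm. Replicating the simulation with population
   parameters resampled under a constant-CV uncertainty model yields a
   distribution of response rates per arm: the *prior* for stage 2.
2. **Conjugate updating.** The simulated response distribution is
   moment-matched to a Beta(α, β) prior. For a proposed per-arm size *n*,
   hypothetical trial data *m* ~ Binomial(*n*, θ) update it in closed form
   to Beta(α + m, β + n − m).
3. **Cost-effectiveness.** A Markov cohort model maps each arm's response
   rate to lifetime discounted QALYs and costs. Setting the incremental net
   monetary benefit λ·ΔQ − ΔC to zero and solving for the new drug's annual
   price gives the payer's maximum reimbursement price (MRP)
   P₂ = [C₁ − C̄₂ + λ(Q₂ − Q₁)] / t₂, with C̄₂ the non-drug cost of the
   new-treatment strategy and t₂ the discounted years of persistence.
4. **ROI.** If P₂ clears the sponsor's minimum viable price, revenue is
   (P₂ − C_PM)·t₂·S(H) over the market horizon, less trial costs
   C_TF + C_TV·2n; otherwise development terminates with zero ROI. The
   expectation over the prior predictive distribution of trial outcomes,
   maximized over the sample-size grid {50, …, 600}, is the design
   recommendation.

Six designs are prebuilt (`default_designs()`): allopurinol 300 or 600 mg vs
febuxostat 80 or 120 mg once daily for 182 days, inclusion at baseline
sUA > 6 or > 8 mg/dL, under a base-case or a reduced input-uncertainty
scenario (the latter standing for the option of first running a small
uncertainty-reduction study).

# The PK/PD model

**Pharmacokinetics.** Linear disposition with first-order absorption: one
compartment for the allopurinol arm (its active moiety behaves like
oxypurinol, with a half-life of over a day), two compartments for
febuxostat. Because the PK is linear, a dosing history's concentration is the
exact superposition of single-dose sum-of-exponentials profiles
(`concentration_profile()`); skipped doses simply contribute nothing. The
removable singularity at coinciding rate constants (e.g. ka equal to an
elimination macro-rate) is handled by a relative 1e-6 perturbation of ka,
far below all comparison tolerances.

**Pharmacodynamics.** A three-state turnover chain of purine metabolism —
hypoxanthine → xanthine → uric acid, each state also cleared renally — with
both xanthine-oxidase steps inhibited by the same Emax term
I(C) = Imax·C/(IC50 + C). Febuxostat additionally stimulates renal excretion
of xanthine via S(C) = Emax_x·C/(EC50_x + C). States are amounts; sUA in
mg/dL is amount/V_ua/10 (the single place the L→dL factor appears). The
chain is linear in its states given C(t), is available in closed form at
steady state (`steady_state_urate()`, the analytic oracle used in tests),
and is linear in the production rate `kin` — so each subject is calibrated
exactly to their observed baseline by one rescaling of `kin`
(`calibrate_baseline()`).

**Covariates and variability.** Weight scales clearances allometrically
(exponent 0.75) and volumes proportionally; age acts log-linearly on the
renal clearances (−1%/year by default) — the conventional pharmacometric
structure, fully config-overridable. Between-subject variability is
lognormal on the parameters named in each drug's `iiv` block. Residual
(intra-individual) variability is deliberately not simulated: the endpoint
is a modelled trough, and adding measurement noise would only blur the
design comparison.

**Numerics.** The reference path (`simulate_urate()`) integrates the chain
with `deSolve::lsoda` at rtol 1e-6 / atol 1e-9. The trial-scale engine is a
compiled cohort integrator: the PK exponentials are propagated *exactly*
through precomputed decay factors (so superposition costs a handful of
multiplies per substep), and the three PD states advance by classical RK4
with at least 20 substeps per day, increased automatically when the
drug-free PD rates are fast (4 × the fastest rate per day). The two paths
agree to well under 1% in the tests. Troughs are sampled at the scheduled
dose time each day, dose administered immediately after sampling.

# Trial execution

Cohorts are drawn from lognormal baseline sUA (median 8.8 mg/dL, σ 0.18 on
the log scale — a gout-trial-like population in which most subjects exceed
6 mg/dL and roughly two thirds exceed 8) and truncated-normal weight and
age. The inclusion rule keeps subjects with baseline *strictly above* the
threshold ("minimum baseline" read as exclusive; the boundary subject is
excluded). Cohorts of exactly N post-inclusion subjects are assembled by
rejection sampling, mirroring trial enrolment to a target size.

Everyone initiates treatment. While on treatment, each dose is taken with a
subject-specific probability drawn from a logit-normal whose *mean* is
exactly the configured 0.9 (the location parameter is solved numerically);
doses are missed independently of one another. Discontinuation is a
Weibull time-to-event with shape 0.5 — the hazard of stopping falls with
time on treatment — and scale 7000 days (≈15% discontinuation over
182 days). A subject who discontinues takes no further doses and *reverts to
their baseline sUA exactly*, hence cannot be a responder unless they entered
below 6 mg/dL. The endpoint is strictly `final sUA < 6`.

# Propagating input uncertainty

Each CTS replicate multiplies every population parameter that has a
configured CV by exp(η), η ~ N(0, log(1 + cv²)) — so the perturbed parameter
has *exactly* the configured coefficient of variation and stays positive.
Both arms within a replicate share the same draw of the uric-acid
physiology (the system block) but take drug-specific PK and potency draws;
a configuration switch fully decouples them. Cohort attributes are resampled
every replicate along with the parameters (a `resample_cohort = FALSE`
switch fixes one cohort instead, isolating parameter uncertainty).
Correlation between input parameters is not modelled.

Replicate response rates are summarized (mean, sample SD, empirical
2.5/97.5 percentiles with linear interpolation) and moment-matched:
ν = m(1 − m)/s² − 1, α = mν, β = (1 − m)ν. The fit is exact, and infeasible
moments (s² ≥ m(1 − m)) or zero spread are flagged as degenerate rather than
silently fitted.

# The economic model

The published pharmacoeconomic model this stage stands in for is not
reproduced verbatim; `markov_spec()` fixes a transparent synthetic default
with the same architecture: three sUA bands (< 6, 6–8, > 8 mg/dL) plus
death, 3-month cycles over a 50-year horizon, 3.5%/year discounting of costs
and QALYs, cycle-start discounting and no half-cycle correction. Band-level
annual flare rates (0.35/1.2/2.5), a £250 cost and 0.012 QALY loss per
flare, band utilities (0.87/0.82/0.76), band management costs and a 2%
annual background mortality are all configuration values, not estimates.
Responders start in the < 6 band; non-responders split 50/50 across the two
upper bands. Patients discontinue inside the model under the *same* Weibull
used in the trial and move to the untreated band distribution, so the trial
and the economic model tell one consistent adherence story. t₂ — discounted
person-years on drug — comes from the same trace, which keeps the price
inversion exact: plugging P₂·t₂ back into the NMB returns zero to machine
precision.

Two useful structural facts are exploited: occupancy is conserved every
cycle (checked to 1e-12), and the model is *linear* in its start occupancy,
so Q(θ) and C(θ) are affine in θ. Stage 3 therefore runs the Markov model
twice (all-responder and all-non-responder starts) and evaluates thousands
of preposterior replicates by interpolation — exactly, not approximately.

The payer threshold defaults to λ = £20,000/QALY, the conservative end of
the usual UK range; the posterior *mean* response feeds the economic model
by default (reimbursement decisions are taken on expected values), with a
`point = "sample"` switch for an uncertainty-averse payer.

# ROI and the sample-size decision

`expected_roi()` draws θ from each arm's prior and couples the binomial
data across the sample-size grid through a shared uniform
(m = F⁻¹(u; n, θ)): common random numbers make the ROI *differences*
between grid points low-noise and make results independent of which grid
subset is evaluated. The termination branch returns exactly zero — no sunk
trial cost — following the payoff model literally; this is economically
debatable (the fixed cost is spent before the decision) but is the stated
rule. Market size is incidence × uptake × horizon, halved for designs that
enrol only above 8 mg/dL (a stricter treatment threshold halves the
eligible population). Trial cost is read as fixed + per-subject × 2n, the
conventional reading that makes the cost grow with the design size. Ties in
expected ROI break towards the smallest trial.

# What the synthetic defaults do and do not show

The drug, population and economic parameter values shipped by
`default_config()` are *synthetic*: chosen once for pharmacological and
economic plausibility (oxypurinol-like kinetics and ~mid-μM potency for the
allopurinol moiety; tight-binding, near-saturated inhibition for
febuxostat; ~700 mg/day urate production, urate distribution volume 12 L,
renal clearance ~8 L/day; generic-priced comparator at £30/year). Under
them the framework reproduces the qualitative decision structure — higher
febuxostat than allopurinol response, a strong penalty to allopurinol from
the stricter inclusion threshold, narrower priors and different optimal
sample sizes under reduced uncertainty — but the *absolute* response rates,
prices and ROI figures are properties of the defaults, not estimates for
any real drug. Passing tests demonstrate the machinery (superposition,
steady states, conjugacy, conservation, price inversion, reproducibility),
not the calibration of any particular parameter set. Real analyses should
drop estimated parameter blocks into the configuration.

# Problem sizes and reproducibility

The package's default run is a scaled-down study: R = 200 CTS replicates of
N = 200 post-inclusion subjects per arm per design, 500 preposterior
replicates per design across the 8-point grid. These sizes give prior-SD
Monte-Carlo error around half a percentage point and keep a full six-design,
four-stage run to a few minutes on one core; the full-fidelity counts
(R = 10,000, N = 1,000) are one flag away (`fidelity = "full"`). All
randomness descends from a single master seed through documented child-seed
derivation (`derive_seeds()`), with replicate-indexed streams, so results
are bit-reproducible and independent of scheduling; pipeline outputs carry
the configuration hash, and byte-identical CSV/JSON outputs under a
repeated seed are part of the test suite.

# Known limitations

* The PD chain, covariate model and economic structure are minimal
  plausible stand-ins; none of their parameter values are estimates.
* Dose implementation is Bernoulli-independent day to day — no weekends,
  streaks or white-coat adherence — and discontinuation is the only form of
  attrition.
* Single market, single payer, no probabilistic sensitivity analysis over
  economic inputs, no safety or regulatory-approval modelling, no
  correlation between input parameters.
* The preposterior ROI surface is flat near its optimum by construction
  (value of information changes slowly in n), so the *location* of the
  optimal n is sensitive to Monte-Carlo noise even when the attained ROI is
  not; the common-random-number coupling mitigates but does not remove
  this.
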