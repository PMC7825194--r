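# Small parameter sets reused across tests. Values are arbitrary but
# physiologically shaped; tests assert relationships, not these numbers.

test_pd <- function(Imax = 0.9, IC50 = 2, Emax_x = 0, EC50_x = 1) {
  pd_params(kin = 700, k_hx_x = 5, k_x_ua = 5, CLr_hx = 20, CLr_x = 20,
            CLr_ua = 8.4, V_hx = 40, V_x = 40, V_ua = 12,
            Imax = Imax, IC50 = IC50, Emax_x = Emax_x, EC50_x = EC50_x)
}

test_pk1 <- function(ka = 15, CL = 30, V1 = 60, F = 0.8) {
  pk_params("one_compartment", ka = ka, CL = CL, V1 = V1, F = F)
}

test_pk2 <- function() {
  pk_params("two_compartment", ka = 20, CL = 250, V1 = 40, Q = 150, V2 = 60,
            F = 0.85)
}

# drug-free chain: slowest timescale under constant concentration C
slowest_halflife <- function(pd, C = 0) {
  I <- pd$Imax * C / (pd$IC50 + C)
  S <- if (pd$Emax_x > 0) pd$Emax_x * C / (pd$EC50_x + C) else 0
  rates <- c(pd$k_hx_x * (1 - I) + pd$CLr_hx / pd$V_hx,
             pd$k_x_ua * (1 - I) + pd$CLr_x / pd$V_x * (1 + S),
             pd$CLr_ua / pd$V_ua)
  log(2) / min(rates)
}

# scaled-down configuration for pipeline wiring tests
tiny_config <- function(seed = 5L, designs = c(1L, 2L)) {
  cfg <- default_config(seed)
  cfg$designs <- cfg$designs[designs]
  cfg$run$replicates <- 10L
  cfg$run$cohort_size <- 30L
  cfg$run$preposterior_replicates <- 40L
  cfg$run$sample_size_grid <- c(50L, 100L)
  cfg
}
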