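# shared fixtures: random admissible rate sets, small synthetic datasets
# and toy regression problems built in code

# n random rate sets, log-uniform in 10^[lo, hi] 1/s
random_rate_sets <- function(n, lo = 4, hi = 9, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- 10^stats::runif(5, lo, hi)
    rate_constant_set(k[1], k[2], k[3], k[4], k[5])
  })
}

# independent linear-algebra solution of the two-compartment system:
# base R eigen() + solve() for the initial-condition amplitudes
eigen_oracle <- function(rates) {
  K_S <- rates$k_r_S1S0 + rates$k_ic_S1S0 + rates$k_isc_S1T1
  K_T <- rates$k_risc_T1S1 + rates$k_isc_T1S0
  M <- matrix(c(-K_S, rates$k_isc_S1T1, rates$k_risc_T1S1, -K_T), 2, 2)
  eg <- eigen(M)
  coef <- solve(eg$vectors, c(1, 0))
  ord <- order(Re(eg$values))          # most negative (fast) first
  lam <- Re(eg$values)[ord]
  amps <- Re(eg$vectors[1, ] * coef)[ord]  # S1(t) = sum amps_i exp(lam_i t)
  integral <- sum(-amps / lam)
  list(lam_fast = lam[1], lam_slow = lam[2],
       phi_total = rates$k_r_S1S0 * integral,
       s1_at = function(t) as.vector(exp(outer(t, lam)) %*% amps))
}

default_synthetic <- function(seed = 1, noise_sd = 8, n_decoys = 0) {
  config <- generator_config(seed = seed, noise_sd = noise_sd,
                             n_decoys = n_decoys)
  sens <- generate_sensitizers(config)
  list(config = config, sensitizers = sens,
       reactions = generate_yields(sens, config))
}

full_feature_spec <- function(extra = character()) {
  feature_spec("s_RC",
               auxiliary = c("E_HOMO", "E_LUMO", "E_S1", "E_T1", "dEST",
                             "f_S1", "dDM"),
               extra = extra)
}

# toy regression problem wrapped as a descriptor matrix
toy_problem <- function(n = 60, p = 4, seed = 42,
                        f = function(X) 3 * X[, 1] + X[, 2] * X[, 3],
                        noise = 0.2) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  colnames(X) <- letters[seq_len(p)]
  as_descriptor_matrix(X, f(X) + stats::rnorm(n, 0, noise))
}
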