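test_that("quantum yield is exactly 1 without non-emissive channels", {
  for (r in random_rate_sets(20, seed = 101)) {
    r$k_ic_S1S0 <- 0
    r$k_isc_T1S0 <- 0
    obs <- decay_eigenmodes(r)
    expect_identical(obs$phi_total, 1)
  }
})

test_that("compartments decouple when reverse ISC is off", {
  obs <- decay_eigenmodes(rate_constant_set(
    k_r_S1S0 = 1e7, k_ic_S1S0 = 1e6, k_isc_S1T1 = 2e7,
    k_risc_T1S1 = 0, k_isc_T1S0 = 1e5))
  expect_equal(obs$tau_prompt, 1 / 3.1e7)
  expect_equal(obs$tau_delayed, 1 / 1e5)
  expect_equal(obs$phi_total, 1e7 / 3.1e7)
  # the slow mode carries no emission: T1 never feeds back into S1
  expect_equal(obs$phi_delayed, 0)
})

test_that("OPS1 experimental rates reproduce its measured prompt lifetime", {
  obs <- decay_eigenmodes(rate_constant_set(
    k_r_S1S0 = 1.7e7, k_isc_S1T1 = 5.1e7, k_risc_T1S1 = 2.7e6))
  expect_lt(abs(obs$tau_prompt * 1e9 - 14.2) / 14.2, 0.01)
  # delayed component on the microsecond scale, as measured
  expect_gt(obs$tau_delayed, 1e-6)
  expect_lt(obs$tau_delayed, 3e-6)
})

test_that("eigenmode solution matches the numerical ODE oracle", {
  for (r in random_rate_sets(25, lo = 4, hi = 8, seed = 7)) {
    obs <- decay_eigenmodes(r)
    t_end <- 40 * obs$tau_delayed
    grid <- c(obs$tau_prompt * c(0.3, 1, 3),
              obs$tau_delayed * c(0.3, 1, 3), t_end)
    pop <- integrate_populations(r, sort(unique(grid)),
                                 rtol = 1e-11, atol = 1e-15)
    # quantum yield by solver-grade quadrature of the S1 population
    phi_quad <- r$k_r_S1S0 * pop$S1_int[nrow(pop)]
    expect_lt(abs(phi_quad / obs$phi_total - 1), 1e-6)
    # full S1 trajectory reconstructed from the reported observables
    amp_p <- obs$phi_prompt / (r$k_r_S1S0 * obs$tau_prompt)
    amp_d <- obs$phi_delayed / (r$k_r_S1S0 * obs$tau_delayed)
    s1_pred <- amp_p * exp(-pop$time / obs$tau_prompt) +
      amp_d * exp(-pop$time / obs$tau_delayed)
    keep <- pop$S1 > 1e-8
    expect_lt(max(abs(s1_pred[keep] / pop$S1[keep] - 1)), 1e-6)
    # populations never exceed the initial excitation
    expect_true(all(pop$S1 + pop$T1 <= 1 + 1e-9))
  }
})

test_that("lifetimes match an independent eigen() linear-algebra oracle", {
  for (r in random_rate_sets(200, seed = 13)) {
    obs <- decay_eigenmodes(r)
    ora <- eigen_oracle(r)
    expect_equal(obs$tau_prompt, -1 / ora$lam_fast, tolerance = 1e-9)
    expect_equal(obs$tau_delayed, -1 / ora$lam_slow, tolerance = 1e-9)
    expect_equal(obs$phi_total, ora$phi_total, tolerance = 1e-9)
  }
})

test_that("a lone radiative channel decays single-exponentially", {
  r <- rate_constant_set(k_r_S1S0 = 1e7)
  t <- seq(1e-9, 5e-7, length.out = 40)
  pop <- integrate_populations(r, t)
  expect_equal(pop$S1, exp(-1e7 * t), tolerance = 1e-8)
  expect_true(all(pop$T1 == 0))
})

test_that("quantum yield decreases in each non-emissive rate", {
  for (r in random_rate_sets(50, seed = 23)) {
    phi0 <- decay_eigenmodes(r)$phi_total
    up_ic <- r; up_ic$k_ic_S1S0 <- r$k_ic_S1S0 * 1.05 + 1
    up_t1 <- r; up_t1$k_isc_T1S0 <- r$k_isc_T1S0 * 1.05 + 1
    expect_lte(decay_eigenmodes(up_ic)$phi_total, phi0 + 1e-12)
    expect_lte(decay_eigenmodes(up_t1)$phi_total, phi0 + 1e-12)
  }
})

test_that("prompt lifetime is bounded by the S1 depopulation rate", {
  for (r in random_rate_sets(100, seed = 31)) {
    obs <- decay_eigenmodes(r)
    K_S <- r$k_r_S1S0 + r$k_ic_S1S0 + r$k_isc_S1T1
    expect_lte(obs$tau_prompt, (1 / K_S) * (1 + 1e-9))
    expect_gte(obs$tau_delayed, obs$tau_prompt)
  }
})

test_that("invalid rate sets and non-decaying systems are rejected", {
  expect_error(rate_constant_set(-1, 0, 1e7), "finite and >= 0")
  expect_error(rate_constant_set(0, 0, 0, 1e5, 1e5), "S1 must decay")
  # S1 <-> T1 shuttle with no loss anywhere
  expect_error(decay_eigenmodes(rate_constant_set(
    k_r_S1S0 = 0, k_ic_S1S0 = 0, k_isc_S1T1 = 1e7, k_risc_T1S1 = 1e6)),
    "non-decaying")
  expect_error(integrate_populations(rate_constant_set(1e7), c(2e-9, 1e-9)),
               "strictly increasing")
})

test_that("inversion recovers k_r in the decoupled case", {
  obs <- photophysics_observables(tau_prompt = 10e-9, phi_prompt = 0.5,
                                  phi_delayed = 0)
  fit <- invert_observables(obs, fixed = list(k_ic_S1S0 = 0,
                                              k_risc_T1S1 = 0))
  expect_equal(fit$rates$k_r_S1S0, 5e7, tolerance = 1e-6)
})

test_that("inversion round-trips the forward model", {
  set.seed(47)
  for (i in 1:20) {
    k <- 10^runif(5, 4, 9)
    truth <- rate_constant_set(k[1], 0, k[3], k[4], k[5])
    fit <- invert_observables(decay_eigenmodes(truth),
                              fixed = list(k_ic_S1S0 = 0))
    free <- c("k_r_S1S0", "k_isc_S1T1", "k_risc_T1S1", "k_isc_T1S0")
    rel <- abs(unlist(fit$rates[free]) / unlist(truth[free]) - 1)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("inversion of OPS1's measured observables recovers its rates", {
  # tau = 14.2 ns / 1.8 us, Phi = 0.94 split delayed-dominant (the known
  # emission pattern of 4CzIPN; the forward model at its reported rates
  # puts ~24% of the emission in the prompt component)
  obs <- photophysics_observables(tau_prompt = 14.2e-9,
                                  tau_delayed = 1.8e-6,
                                  phi_prompt = 0.24, phi_delayed = 0.70)
  fit <- invert_observables(obs, fixed = list(k_ic_S1S0 = 0))
  reported <- c(k_r_S1S0 = 1.7e7, k_isc_S1T1 = 5.1e7, k_risc_T1S1 = 2.7e6)
  for (nm in names(reported)) {
    ratio <- fit$rates[[nm]] / reported[[nm]]
    expect_gt(ratio, 1 / 1.5)
    expect_lt(ratio, 1.5)
  }
})

test_that("under-identified inversion is refused with the free names", {
  obs <- photophysics_observables(tau_prompt = 10e-9, phi_prompt = 0.5)
  err <- tryCatch(invert_observables(obs, fixed = list()),
                  error = conditionMessage)
  expect_match(err, "under-identified")
  expect_match(err, "k_risc_T1S1")
})

test_that("observables round-trip through delimited text", {
  obs <- lapply(random_rate_sets(5, seed = 61), decay_eigenmodes)
  names(obs) <- sprintf("OPS%03d", 1:5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_observables(obs, f)
  back <- read_observables(f)
  expect_equal(back, obs)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(header, c("id", "tau_prompt_s", "tau_delayed_s",
                         "phi_prompt", "phi_delayed"))
  expect_error(read_observables(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")),
    "tau_prompt_s")
})

test_that("detailed-balance RISC surrogate behaves as an Arrhenius factor", {
  expect_identical(detailed_balance_risc(5.1e7, 0), 5.1e7)
  # OPS1: 0.08 eV gap at room temperature, same order as the measured rate
  est <- detailed_balance_risc(5.1e7, 0.08, 298)
  expect_equal(est, 2.26e6, tolerance = 0.01)
  expect_gt(est / 2.7e6, 0.1)
  expect_lt(est / 2.7e6, 10)
  # freezing out the up-conversion
  temps <- c(298, 100, 30, 10, 1)
  vals <- detailed_balance_risc(1e8, 0.1, temps)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[5], 1e-300)
})
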