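#' Excited-state rate constants of one sensitizer
#'
#' Bundles the five first-order rate constants of the three-state
#' (S0, S1, T1) kinetic scheme: radiative and internal-conversion decay of
#' S1, intersystem crossing S1 -> T1, reverse intersystem crossing
#' T1 -> S1, and non-radiative intersystem crossing T1 -> S0. The radiative
#' T1 -> S0 (phosphorescence) channel is deliberately absent: it is
#' negligible for purely organic sensitizers.
#'
#' @param k_r_S1S0 radiative S1 -> S0 rate, 1/s.
#' @param k_ic_S1S0 internal-conversion S1 -> S0 rate, 1/s.
#' @param k_isc_S1T1 intersystem-crossing S1 -> T1 rate, 1/s.
#' @param k_risc_T1S1 reverse intersystem-crossing T1 -> S1 rate, 1/s.
#' @param k_isc_T1S0 intersystem-crossing T1 -> S0 rate, 1/s.
#' @return An object of class `rate_constant_set` (named list of the five
#'   rates).
#' @examples
#' rate_constant_set(k_r_S1S0 = 1.7e7, k_isc_S1T1 = 5.1e7,
#'                   k_risc_T1S1 = 2.7e6)
#' @export
rate_constant_set <- function(k_r_S1S0 = 0, k_ic_S1S0 = 0, k_isc_S1T1 = 0,
                              k_risc_T1S1 = 0, k_isc_T1S0 = 0) {
  k <- c(k_r_S1S0 = as.numeric(k_r_S1S0), k_ic_S1S0 = as.numeric(k_ic_S1S0),
         k_isc_S1T1 = as.numeric(k_isc_S1T1),
         k_risc_T1S1 = as.numeric(k_risc_T1S1),
         k_isc_T1S0 = as.numeric(k_isc_T1S0))
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("all five rate constants must be finite and >= 0", call. = FALSE)
  }
  if (k[["k_r_S1S0"]] + k[["k_ic_S1S0"]] + k[["k_isc_S1T1"]] <= 0) {
    stop("S1 must decay: at least one of k_r_S1S0, k_ic_S1S0, k_isc_S1T1 ",
         "must be > 0", call. = FALSE)
  }
  structure(as.list(k), class = "rate_constant_set")
}

#' @export
print.rate_constant_set <- function(x, ...) {
  cat("<rate_constant_set> (1/s)\n")
  for (nm in RATE_NAMES) cat(sprintf("  %-12s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

as_rate_constant_set <- function(x) {
  if (inherits(x, "rate_constant_set")) return(x)
  x <- as.list(x)
  stopifnot(all(RATE_NAMES %in% names(x)))
  do.call(rate_constant_set, x[RATE_NAMES])
}

#' Emission observables of a three-state sensitizer
#'
#' @param tau_prompt prompt emission lifetime, s.
#' @param tau_delayed delayed emission lifetime, s (`NA` when the triplet
#'   has no decay channel and delayed emission is absent).
#' @param phi_prompt prompt emission quantum yield.
#' @param phi_delayed delayed emission quantum yield.
#' @return An object of class `photophysics_observables`.
#' @export
photophysics_observables <- function(tau_prompt = NA_real_,
                                     tau_delayed = NA_real_,
                                     phi_prompt = NA_real_,
                                     phi_delayed = NA_real_) {
  obs <- list(tau_prompt = as.numeric(tau_prompt),
              tau_delayed = as.numeric(tau_delayed),
              phi_prompt = as.numeric(phi_prompt),
              phi_delayed = as.numeric(phi_delayed))
  obs$phi_total <- if (is.na(obs$phi_prompt)) NA_real_ else {
    obs$phi_prompt + ifelse(is.na(obs$phi_delayed), 0, obs$phi_delayed)
  }
  tol <- 1e-9
  if (!is.na(obs$tau_prompt) && obs$tau_prompt <= 0) {
    stop("tau_prompt must be > 0", call. = FALSE)
  }
  if (!is.na(obs$tau_prompt) && !is.na(obs$tau_delayed) &&
      obs$tau_delayed < obs$tau_prompt * (1 - 1e-12)) {
    stop("tau_delayed must be >= tau_prompt", call. = FALSE)
  }
  phis <- c(obs$phi_prompt, obs$phi_delayed, obs$phi_total)
  phis <- phis[!is.na(phis)]
  if (any(phis < -tol) || any(phis > 1 + tol)) {
    stop("quantum yields must lie in [0, 1]", call. = FALSE)
  }
  structure(obs, class = "photophysics_observables")
}

#' @export
print.photophysics_observables <- function(x, ...) {
  cat("<photophysics_observables>\n")
  cat(sprintf("  tau_prompt  %.4g s\n", x$tau_prompt))
  cat(sprintf("  tau_delayed %.4g s\n", x$tau_delayed))
  cat(sprintf("  phi_prompt  %.4g | phi_delayed %.4g | phi_total %.4g\n",
              x$phi_prompt, x$phi_delayed, x$phi_total))
  invisible(x)
}

#' Biexponential decay observables from rate constants
#'
#' Solves the coupled two-compartment linear kinetics of the S1/T1
#' populations,
#' \deqn{d[S1]/dt = -(k_r + k_{ic} + k_{isc})[S1] + k_{risc}[T1]}
#' \deqn{d[T1]/dt = k_{isc}[S1] - (k_{risc} + k_{isc,T1S0})[T1],}
#' in closed form. The two (real, negative) eigenvalues of the rate matrix
#' give the prompt and delayed lifetimes; the emission quantum yield is
#' \eqn{k_r \int_0^\infty [S1]\,dt} with \eqn{[S1](0) = 1}, split into
#' prompt/delayed shares by the fast/slow eigenmode decomposition of the
#' integral.
#'
#' @param rates a [rate_constant_set()].
#' @return A [photophysics_observables()] object. When the triplet has no
#'   decay channel at all (`k_risc_T1S1 = k_isc_T1S0 = 0`) the delayed
#'   lifetime is reported as `NA` and the delayed yield as 0. When the two
#'   eigenvalues coincide within a relative 1e-12 a single lifetime is
#'   reported for both components.
#' @examples
#' # OPS1-like TADF emitter: microsecond delayed component
#' decay_eigenmodes(rate_constant_set(k_r_S1S0 = 1.7e7, k_isc_S1T1 = 5.1e7,
#'                                    k_risc_T1S1 = 2.7e6))
#' @export
decay_eigenmodes <- function(rates) {
  rates <- as_rate_constant_set(rates)
  k_r <- rates$k_r_S1S0
  K_S <- k_r + rates$k_ic_S1S0 + rates$k_isc_S1T1   # total S1 depopulation
  K_T <- rates$k_risc_T1S1 + rates$k_isc_T1S0       # total T1 depopulation
  k_isc <- rates$k_isc_S1T1
  k_risc <- rates$k_risc_T1S1

  if (K_T == 0) {
    # triplet is a dark sink (or never populated): S1 decays alone
    tau_p <- 1 / K_S
    phi_tot <- k_r / K_S
    return(photophysics_observables(tau_prompt = tau_p,
                                    tau_delayed = NA_real_,
                                    phi_prompt = phi_tot, phi_delayed = 0))
  }

  det_M <- K_S * K_T - k_isc * k_risc  # product of -eigenvalues
  if (det_M <= 0) {
    stop("non-decaying system: S1/T1 cycle has no loss channel ",
         "(K_S*K_T - k_isc*k_risc <= 0)", call. = FALSE)
  }
  disc <- sqrt((K_S - K_T)^2 + 4 * k_isc * k_risc)
  lam_fast <- -(K_S + K_T + disc) / 2
  lam_slow <- -(K_S + K_T - disc) / 2

  # with no non-emissive channel every excitation eventually emits;
  # evaluate that case exactly instead of through the cancelling ratio
  phi_tot <- if (rates$k_ic_S1S0 == 0 && rates$k_isc_T1S0 == 0) 1 else
    k_r * K_T / det_M

  if (disc <= 1e-12 * (K_S + K_T) / 2) {
    # degenerate eigenvalues: a single observable lifetime
    tau <- -1 / lam_fast
    return(photophysics_observables(tau_prompt = tau, tau_delayed = tau,
                                    phi_prompt = phi_tot, phi_delayed = 0))
  }

  # [S1](t) = A exp(lam_fast t) + B exp(lam_slow t), S1(0)=1, S1'(0)=-K_S
  A <- (K_S + lam_slow) / (lam_slow - lam_fast)
  B <- 1 - A
  raw_p <- k_r * A * (-1 / lam_fast)
  raw_d <- k_r * B * (-1 / lam_slow)
  # split the exact total by the eigenmode shares so the parts sum to it
  phi_p <- phi_tot * raw_p / (raw_p + raw_d)
  photophysics_observables(tau_prompt = -1 / lam_fast,
                           tau_delayed = -1 / lam_slow,
                           phi_prompt = phi_p, phi_delayed = phi_tot - phi_p)
}

#' Numerically integrate the S1/T1 populations
#'
#' Brute-force numerical solution of the same two-compartment linear system
#' as [decay_eigenmodes()], with \eqn{[S1](0) = 1}, \eqn{[T1](0) = 0}.
#' Serves as the independent oracle for the closed-form eigenmode solution
#' and for quantum-yield quadrature.
#'
#' @param rates a [rate_constant_set()].
#' @param t_grid strictly increasing vector of times (s), all >= 0.
#' @param rtol,atol solver tolerances passed to [deSolve::ode()].
#' @return A tibble with columns `time`, `S1`, `T1` and `S1_int`
#'   (the running integral of the S1 population, for quantum-yield
#'   quadrature).
#' @export
integrate_populations <- function(rates, t_grid, rtol = 1e-10, atol = 1e-12) {
  rates <- as_rate_constant_set(rates)
  t_grid <- as.numeric(t_grid)
  if (any(t_grid < 0) || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing and non-negative", call. = FALSE)
  }
  K_S <- rates$k_r_S1S0 + rates$k_ic_S1S0 + rates$k_isc_S1T1
  K_T <- rates$k_risc_T1S1 + rates$k_isc_T1S0
  M <- matrix(c(-K_S, rates$k_isc_S1T1, rates$k_risc_T1S1, -K_T), 2, 2)
  # third state accumulates int_0^t [S1] dt for quantum-yield quadrature
  deriv <- function(t, y, parms) {
    list(c(as.vector(M %*% y[1:2]), y[1]))
  }
  jac <- function(t, y, parms) {
    rbind(cbind(M, c(0, 0)), c(1, 0, 0))
  }
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- try(deSolve::ode(y = c(S1 = 1, T1 = 0, S1_int = 0), times = times,
                          func = deriv, parms = NULL, jacfunc = jac,
                          jactype = "fullusr", method = "lsoda",
                          rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") ||
      attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    stop(sprintf(paste0("stiff-solver failure (rate magnitudes: K_S=%.3g, ",
                        "K_T=%.3g 1/s); consider rescaling time"),
                 K_S, K_T), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("time", "S1", "T1", "S1_int")
  out[match(t_grid, out$time), ]
}

#' Thermally activated reverse intersystem crossing surrogate
#'
#' Detailed-balance (Boltzmann) estimate of the T1 -> S1 up-conversion rate
#' from the forward ISC rate and the singlet-triplet gap:
#' \eqn{k_{risc} = k_{isc} \exp(-\Delta E_{ST} / k_B T)}. This is the
#' simple activation picture of thermally activated delayed fluorescence,
#' used by the synthetic generator as a physically plausible coupling
#' between `k_risc_T1S1`, `k_isc_S1T1` and the gap.
#'
#' @param k_isc_S1T1 forward ISC rate, 1/s.
#' @param delta_E_ST singlet-triplet energy gap, eV (>= 0).
#' @param temperature temperature, K.
#' @return Estimated reverse-ISC rate, 1/s.
#' @examples
#' detailed_balance_risc(5.1e7, 0.08, 298)  # ~2.3e6 1/s
#' @export
detailed_balance_risc <- function(k_isc_S1T1, delta_E_ST,
                                  temperature = 298.15) {
  stopifnot(all(k_isc_S1T1 >= 0), all(delta_E_ST >= 0), all(temperature > 0))
  k_isc_S1T1 * exp(-delta_E_ST / (K_BOLTZMANN_EV * temperature))
}

#' Serialize observables to/from delimited text
#'
#' Columns are named exactly `tau_prompt_s`, `tau_delayed_s`, `phi_prompt`,
#' `phi_delayed` (lifetimes in seconds); an optional leading `id` column
#' carries row identifiers. Round-trips are exact.
#'
#' @param obs_list list of [photophysics_observables()] (optionally named).
#' @param path CSV path.
#' @return `write_observables` invisibly returns the path;
#'   `read_observables` returns a named list of observables.
#' @export
write_observables <- function(obs_list, path) {
  stopifnot(all(vapply(obs_list, inherits, logical(1),
                       "photophysics_observables")))
  ids <- names(obs_list) %||% sprintf("obs%03d", seq_along(obs_list))
  tab <- tibble::tibble(
    id = ids,
    tau_prompt_s = vapply(obs_list, `[[`, 0, "tau_prompt"),
    tau_delayed_s = vapply(obs_list, `[[`, 0, "tau_delayed"),
    phi_prompt = vapply(obs_list, `[[`, 0, "phi_prompt"),
    phi_delayed = vapply(obs_list, `[[`, 0, "phi_delayed"))
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("tau_prompt_s", "tau_delayed_s", "phi_prompt", "phi_delayed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("observables table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    photophysics_observables(tau_prompt = tab$tau_prompt_s[i],
                             tau_delayed = tab$tau_delayed_s[i],
                             phi_prompt = tab$phi_prompt[i],
                             phi_delayed = tab$phi_delayed[i])
  })
  names(out) <- if ("id" %in% names(tab)) tab$id else
    sprintf("obs%03d", seq_len(nrow(tab)))
  out
}

# run code with a private RNG stream, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Estimate rate constants from emission observables
#'
#' Numerically inverts the forward model [decay_eigenmodes()]: finds the
#' free rate constants whose predicted lifetimes and quantum yields
#' reproduce the supplied observables, by bounded least squares in
#' log10-rate space (rates span more than ten decades, so the search is
#' performed on exponents within \[1e-2, 1e12\] 1/s).
#'
#' With five unknown rates but at most four independent observables
#' (two lifetimes plus the prompt/delayed yield split), at least one rate
#' must be fixed. By default `k_ic_S1S0` is fixed to 0, attributing any
#' sub-unity total yield to the triplet loss channel `k_isc_T1S0`; pass a
#' different `fixed` list to change that convention.
#'
#' When all four of (tau_prompt, tau_delayed, phi_prompt, phi_delayed) are
#' observed and exactly `k_ic_S1S0` is fixed, the inverse is computed in
#' closed form first (the amplitude split of the biexponential determines
#' the S1 depopulation rate; the eigenvalue sum and product then yield the
#' triplet rates) and the optimizer only polishes it.
#'
#' @param obs a [photophysics_observables()] object; `NA` fields are
#'   treated as unobserved.
#' @param fixed named list of rates held fixed (default `k_ic_S1S0 = 0`).
#' @param n_restarts number of deterministic multi-start perturbations.
#' @return A list with elements `rates` (the recovered
#'   [rate_constant_set()]), `residual` (root of the final sum of squared
#'   observable residuals) and `converged`.
#' @export
invert_observables <- function(obs, fixed = list(k_ic_S1S0 = 0),
                               n_restarts = 12) {
  stopifnot(inherits(obs, "photophysics_observables"))
  fixed <- as.list(fixed)
  if (!all(names(fixed) %in% RATE_NAMES)) {
    stop("unknown rate name in `fixed`: ",
         paste(setdiff(names(fixed), RATE_NAMES), collapse = ", "),
         call. = FALSE)
  }
  free <- setdiff(RATE_NAMES, names(fixed))

  have_tau_p <- !is.na(obs$tau_prompt)
  have_tau_d <- !is.na(obs$tau_delayed)
  have_phi_p <- !is.na(obs$phi_prompt)
  have_phi_d <- !is.na(obs$phi_delayed)
  n_indep <- have_tau_p + have_tau_d +
    if (have_phi_p && have_phi_d) 2L else if (have_phi_p || have_phi_d ||
                                              !is.na(obs$phi_total)) 1L else 0L
  if (length(free) > n_indep) {
    stop("under-identified inversion: ", length(free), " free rates (",
         paste(free, collapse = ", "), ") but only ", n_indep,
         " independent observables; fix more rates", call. = FALSE)
  }

  residuals_for <- function(logk) {
    k <- as.list(fixed)
    k[free] <- as.list(10^logk)
    pred <- try(decay_eigenmodes(do.call(rate_constant_set, k[RATE_NAMES])),
                silent = TRUE)
    if (inherits(pred, "try-error")) return(rep(1e3, max(n_indep, 1)))
    r <- numeric(0)
    if (have_tau_p) r <- c(r, log(pred$tau_prompt / obs$tau_prompt))
    if (have_tau_d) {
      if (is.na(pred$tau_delayed)) return(rep(1e3, max(n_indep, 1)))
      r <- c(r, log(pred$tau_delayed / obs$tau_delayed))
    }
    if (have_phi_p && have_phi_d) {
      r <- c(r, pred$phi_prompt - obs$phi_prompt,
             pred$phi_delayed - obs$phi_delayed)
    } else if (!is.na(obs$phi_total)) {
      r <- c(r, pred$phi_total - obs$phi_total)
    }
    r
  }
  objective <- function(logk) sum(residuals_for(logk)^2)

  # heuristic initial point from the decoupled (weak-RISC) approximation
  init <- c(k_r_S1S0 = 7, k_ic_S1S0 = 5, k_isc_S1T1 = 7,
            k_risc_T1S1 = 5, k_isc_T1S0 = 4)
  if (have_tau_p) {
    K_S0 <- 1 / obs$tau_prompt
    phi0 <- if (have_phi_p) max(obs$phi_prompt, 1e-3) else
      if (!is.na(obs$phi_total)) max(obs$phi_total, 1e-3) else 0.5
    init["k_r_S1S0"] <- log10(phi0 * K_S0)
    init["k_isc_S1T1"] <- log10(max(K_S0 * (1 - phi0), 0.05 * K_S0))
    init["k_ic_S1S0"] <- log10(0.05 * K_S0)
  }
  if (have_tau_d) {
    init["k_risc_T1S1"] <- log10(1 / obs$tau_delayed)
    init["k_isc_T1S0"] <- log10(0.3 / obs$tau_delayed)
  }
  # closed-form solution of the full biexponential inverse problem:
  # the prompt/delayed amplitude split pins K_S and k_r; the eigenvalue
  # sum and product then give K_T, k_risc and k_isc_T1S0
  closed_form <- NULL
  if (have_tau_p && have_tau_d && have_phi_p && have_phi_d &&
      obs$phi_delayed > 0 && obs$phi_prompt > 0) {
    lam_f <- -1 / obs$tau_prompt
    lam_s <- -1 / obs$tau_delayed
    ratio <- (obs$phi_prompt * obs$tau_delayed) /
      (obs$phi_delayed * obs$tau_prompt)   # = A/B
    A <- ratio / (1 + ratio)
    B <- 1 - A
    K_S <- -(A * lam_f + B * lam_s)
    K_T <- -(lam_f + lam_s) - K_S
    k_r <- obs$phi_prompt / (A * obs$tau_prompt)
    k_ic_fix <- if ("k_ic_S1S0" %in% names(fixed)) fixed$k_ic_S1S0 else 0
    k_isc <- K_S - k_r - k_ic_fix
    if (k_isc > 0 && K_T > 0) {
      k_risc <- (K_S * K_T - lam_f * lam_s) / k_isc
      k_t1s0 <- K_T - k_risc
      cand <- c(k_r_S1S0 = k_r, k_ic_S1S0 = k_ic_fix, k_isc_S1T1 = k_isc,
                k_risc_T1S1 = k_risc, k_isc_T1S0 = k_t1s0)
      if (all(cand[free] > 0)) closed_form <- log10(cand[free])
    }
  }

  starts <- list(pmin(pmax(init[free], -2), 12))
  if (!is.null(closed_form)) {
    starts <- c(list(pmin(pmax(closed_form, -2), 12)), starts)
  }
  if (n_restarts > 0) {
    pert <- with_local_seed(1405, {
      matrix(stats::runif(n_restarts * length(free), -2.5, 2.5),
             nrow = n_restarts)
    })
    base_start <- init[free]
    for (i in seq_len(n_restarts)) {
      starts[[length(starts) + 1]] <-
        pmin(pmax(base_start + pert[i, ], -2), 12)
    }
  }

  best <- NULL
  ctrl <- list(eval.max = 5000, iter.max = 2000, abs.tol = 0,
               rel.tol = 1e-15, x.tol = 1e-15)
  for (s in starts) {
    fit <- stats::nlminb(s, objective, lower = -2, upper = 12,
                         control = ctrl)
    # polish
    fit <- stats::nlminb(fit$par, objective, lower = -2, upper = 12,
                         control = ctrl)
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (best$objective < 1e-20) break
  }
  if (best$objective > 1e-6) {
    stop(sprintf(paste0("inversion did not converge: final residual norm ",
                        "%.3g exceeds tolerance"), sqrt(best$objective)),
         call. = FALSE)
  }
  k <- as.list(fixed)
  k[free] <- as.list(10^best$par)
  list(rates = do.call(rate_constant_set, k[RATE_NAMES]),
       residual = sqrt(best$objective),
       converged = best$objective < 1e-12)
}
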