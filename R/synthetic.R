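# Synthetic sensitizer populations and reaction-yield datasets.
#
# The generator emulates the statistical structure the analysis assumes:
# five excited-state rate constants spanning many decades (with the
# reverse-ISC rate tied to the forward ISC rate and the singlet-triplet
# gap through a thermally activated surrogate), strongly correlated
# frontier-orbital energies, and yields driven by branching-ratio windows
# on the triplet channels, an internal-conversion penalty, a
# frontier-orbital energy window and the singlet-triplet gap.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a population of 60 sensitizers screened against 5
#' reactions of one mechanistic family (energy transfer), with a 0.86
#' HOMO/LUMO correlation and 8 yield-points of observation noise.
#'
#' @param n_sensitizers number of sensitizers.
#' @param reaction_ids reaction labels.
#' @param reaction_families named character vector mapping each reaction to
#'   `"energy_transfer"` (yield window on E_HOMO) or `"redox"` (window on
#'   E_LUMO); defaults to all energy transfer.
#' @param seed integer seed; generation is deterministic given the config.
#' @param rate_log10_ranges list of `c(lo, hi)` log10 bounds (1/s) for the
#'   four directly sampled rates (`k_risc_T1S1` is derived).
#' @param electronic means/SDs of the electronic descriptors and the
#'   HOMO/LUMO correlation.
#' @param risc_noise_sdlog10 SD (decades) of the lognormal scatter applied
#'   to the detailed-balance reverse-ISC estimate, truncated at 3 SD.
#' @param temperature_K temperature for the reverse-ISC surrogate.
#' @param noise_sd Gaussian yield noise, percentage points.
#' @param mechanism weights and window parameters of the latent yield
#'   score (logit units); see [generate_yields()].
#' @param n_decoys number of pure-noise decoy descriptor columns.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_sensitizers = 60,
                             reaction_ids = paste0("CO-", letters[1:5]),
                             reaction_families = NULL,
                             seed = 1,
                             rate_log10_ranges = list(
                               k_r_S1S0 = c(6, 7.7),
                               k_ic_S1S0 = c(4, 8),
                               k_isc_S1T1 = c(5, 9),
                               k_isc_T1S0 = c(2, 6)),
                             electronic = list(
                               E_HOMO_mean = -5.9, E_HOMO_sd = 0.35,
                               E_LUMO_mean = -1.8, E_LUMO_sd = 0.35,
                               homo_lumo_cor = 0.86,
                               E_S1_mean = 2.9, E_S1_sd = 0.25,
                               dEST_meanlog = log(0.15), dEST_sdlog = 0.6,
                               f_S1_meanlog = log(0.2), f_S1_sdlog = 0.8,
                               dDM_mean = 3, dDM_sd = 2),
                             risc_noise_sdlog10 = 0.5,
                             temperature_K = 298,
                             noise_sd = 8,
                             mechanism = list(
                               w_risc = 3.0, risc_window = c(-5, -2),
                               risc_soft = 0.5,
                               w_t1s0 = 2.5, t1s0_window = c(-4.5, -1.5),
                               t1s0_soft = 0.5,
                               w_ic = 3.0,
                               w_orb = 2.5,
                               homo_window = c(-6.25, -5.55),
                               lumo_window = c(-2.15, -1.45),
                               orb_soft = 0.15,
                               w_dest = 4.0,
                               intercept_range = c(-1.5, 1.5),
                               offset = -2.6),
                             n_decoys = 0) {
  if (is.null(reaction_families)) {
    reaction_families <- stats::setNames(
      rep("energy_transfer", length(reaction_ids)), reaction_ids)
  }
  for (rg in rate_log10_ranges) {
    stopifnot(length(rg) == 2, all(is.finite(rg)), rg[1] < rg[2])
  }
  stopifnot(abs(electronic$homo_lumo_cor) < 1, noise_sd >= 0,
            n_sensitizers >= 1, length(reaction_ids) >= 1,
            all(reaction_ids %in% names(reaction_families)),
            all(reaction_families %in% c("energy_transfer", "redox")))
  structure(list(n_sensitizers = n_sensitizers, reaction_ids = reaction_ids,
                 reaction_families = reaction_families, seed = seed,
                 rate_log10_ranges = rate_log10_ranges,
                 electronic = electronic,
                 risc_noise_sdlog10 = risc_noise_sdlog10,
                 temperature_K = temperature_K, noise_sd = noise_sd,
                 mechanism = mechanism, n_decoys = n_decoys),
            class = "generator_config")
}

#' Generate a synthetic sensitizer population
#'
#' Frontier-orbital energies are drawn from a correlated bivariate normal;
#' the S1 energy and singlet-triplet gap set `E_T1 = E_S1 - dEST`; the
#' four directly sampled rate constants are log-uniform within their
#' configured decade ranges; and the reverse-ISC rate is the
#' detailed-balance surrogate [detailed_balance_risc()] times truncated
#' lognormal scatter, so small gaps come with fast up-conversion.
#'
#' @param config a [generator_config()].
#' @return Tibble in the sensitizer-table schema (plus `decoy_*` columns
#'   when configured), with ids `OPS001`, `OPS002`, ...
#' @export
generate_sensitizers <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_sensitizers
  el <- config$electronic
  with_local_seed(config$seed, {
    Sigma <- matrix(c(el$E_HOMO_sd^2,
                      el$homo_lumo_cor * el$E_HOMO_sd * el$E_LUMO_sd,
                      el$homo_lumo_cor * el$E_HOMO_sd * el$E_LUMO_sd,
                      el$E_LUMO_sd^2), 2, 2)
    hl <- MASS::mvrnorm(n, mu = c(el$E_HOMO_mean, el$E_LUMO_mean),
                        Sigma = Sigma)
    # orbital ordering: resample the rare draws with E_HOMO >= E_LUMO
    bad <- which(hl[, 1] >= hl[, 2])
    while (length(bad) > 0) {
      hl[bad, ] <- MASS::mvrnorm(length(bad),
                                 mu = c(el$E_HOMO_mean, el$E_LUMO_mean),
                                 Sigma = Sigma)
      bad <- bad[hl[bad, 1] >= hl[bad, 2]]
    }
    E_S1 <- pmax(stats::rnorm(n, el$E_S1_mean, el$E_S1_sd), 1.5)
    dEST <- pmin(stats::rlnorm(n, el$dEST_meanlog, el$dEST_sdlog), 0.8)
    E_T1 <- E_S1 - dEST
    f_S1 <- stats::rlnorm(n, el$f_S1_meanlog, el$f_S1_sdlog)
    dDM <- abs(stats::rnorm(n, el$dDM_mean, el$dDM_sd))

    draw_rate <- function(nm) {
      rg <- config$rate_log10_ranges[[nm]]
      10^stats::runif(n, rg[1], rg[2])
    }
    k_r <- draw_rate("k_r_S1S0")
    k_ic <- draw_rate("k_ic_S1S0")
    k_isc <- draw_rate("k_isc_S1T1")
    k_t1s0 <- draw_rate("k_isc_T1S0")
    eps <- pmin(pmax(stats::rnorm(n, 0, config$risc_noise_sdlog10),
                     -3 * config$risc_noise_sdlog10),
                3 * config$risc_noise_sdlog10)
    k_risc <- detailed_balance_risc(k_isc, dEST, config$temperature_K) *
      10^eps

    out <- tibble::tibble(
      sensitizer_id = sprintf("OPS%03d", seq_len(n)),
      k_r_S1S0 = k_r, k_ic_S1S0 = k_ic, k_isc_S1T1 = k_isc,
      k_risc_T1S1 = k_risc, k_isc_T1S0 = k_t1s0,
      E_HOMO_eV = hl[, 1], E_LUMO_eV = hl[, 2],
      E_S1_eV = E_S1, E_T1_eV = E_T1, dEST_eV = dEST,
      f_S1 = f_S1, dDM_debye = dDM)
    if (config$n_decoys > 0) {
      for (j in seq_len(config$n_decoys)) {
        out[[paste0("decoy_", j)]] <- stats::rnorm(n)
      }
    }
    out
  })
}

# smooth band-pass window in (0, 1)
soft_window <- function(z, lo, hi, soft) {
  stats::plogis((z - lo) / soft) * stats::plogis((hi - z) / soft)
}

# latent mechanism score (logit units) for each sensitizer x reaction
latent_yield_score <- function(sensitizers, config) {
  mech <- config$mechanism
  rates <- as.matrix(sensitizers[RATE_NAMES])
  s <- rates / rowSums(rates)
  colnames(s) <- SCALED_NAMES
  base <- mech$w_risc * soft_window(log10(s[, "s_k_risc_T1S1"]),
                                    mech$risc_window[1],
                                    mech$risc_window[2], mech$risc_soft) +
    mech$w_t1s0 * soft_window(log10(s[, "s_k_isc_T1S0"]),
                              mech$t1s0_window[1], mech$t1s0_window[2],
                              mech$t1s0_soft) -
    mech$w_ic * s[, "s_k_ic_S1S0"] -
    mech$w_dest * sensitizers$dEST_eV + mech$offset
  orb_et <- mech$w_orb * soft_window(sensitizers$E_HOMO_eV,
                                     mech$homo_window[1],
                                     mech$homo_window[2], mech$orb_soft)
  orb_rx <- mech$w_orb * soft_window(sensitizers$E_LUMO_eV,
                                     mech$lumo_window[1],
                                     mech$lumo_window[2], mech$orb_soft)
  intercepts <- seq(mech$intercept_range[1], mech$intercept_range[2],
                    length.out = length(config$reaction_ids))
  names(intercepts) <- config$reaction_ids
  score <- function(reaction_id) {
    fam <- config$reaction_families[[reaction_id]]
    base + (if (fam == "energy_transfer") orb_et else orb_rx) +
      intercepts[[reaction_id]]
  }
  vapply(config$reaction_ids, score, numeric(nrow(sensitizers)))
}

#' Generate reaction yields for a sensitizer population
#'
#' The latent score of each (sensitizer, reaction) pair sums band-pass
#' windows on the log branching ratios of the two triplet channels
#' (reverse ISC and T1 -> S0 ISC), a linear penalty in the
#' internal-conversion branching ratio, a band-pass window on E_HOMO
#' (energy-transfer reactions) or E_LUMO (redox reactions), a decreasing
#' term in the singlet-triplet gap, and a reaction-specific intercept.
#' Yields are `clip(100 * plogis(score) + N(0, noise_sd), 0, 100)`.
#'
#' @param sensitizers tibble from [generate_sensitizers()].
#' @param config the same [generator_config()].
#' @return Reactions tibble (`sensitizer_id`, `reaction_id`,
#'   `yield_percent`).
#' @export
generate_yields <- function(sensitizers, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"), nrow(sensitizers) > 0)
  scores <- latent_yield_score(sensitizers, config)
  with_local_seed(config$seed + 7919L, {
    rows <- lapply(config$reaction_ids, function(r) {
      mu <- 100 * stats::plogis(scores[, r])
      y <- mu + stats::rnorm(nrow(sensitizers), 0, config$noise_sd)
      tibble::tibble(sensitizer_id = sensitizers$sensitizer_id,
                     reaction_id = r,
                     yield_percent = pmin(pmax(y, 0), 100))
    })
    out <- dplyr::bind_rows(rows)
    out[order(out$sensitizer_id, out$reaction_id), ]
  })
}

#' Write a pinned synthetic fixture dataset
#'
#' `"tiny"` is 8 sensitizers x 2 reactions (16 yield rows), `"default"`
#' the full 60 x 5 design; both use a pinned seed so regeneration is
#' reproducible.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir output directory.
#' @return Invisibly, the written file paths (see [write_dataset()]).
#' @export
make_fixture <- function(size = c("tiny", "default"),
                         dir = tempfile("fixture")) {
  size <- match.arg(size)
  config <- switch(size,
    tiny = generator_config(n_sensitizers = 8,
                            reaction_ids = c("CO-a", "CO-b"), seed = 20211),
    default = generator_config(seed = 20211))
  sens <- generate_sensitizers(config)
  reactions <- generate_yields(sens, config)
  write_dataset(sens, reactions, dir, prefix = paste0(size, "_synthetic"))
}
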