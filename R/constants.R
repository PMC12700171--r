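#' @useDynLib photoyield, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

RATE_NAMES <- c("k_r_S1S0", "k_ic_S1S0", "k_isc_S1T1", "k_risc_T1S1",
                "k_isc_T1S0")

# Boltzmann constant, eV/K
K_BOLTZMANN_EV <- 8.617333e-5
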