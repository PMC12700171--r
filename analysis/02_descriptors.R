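#!/usr/bin/env Rscript
# Build the descriptor sets: branching-ratio (s_RC) and log-rate (RC)
# blocks, the seven electronic descriptors, and the one-hot reaction
# encoding; write the assembled model matrix.

suppressMessages({
  library(photoyield)
  library(readr)
})

ds <- read_dataset("results/data/default_sensitizers.csv",
                   "results/data/default_reactions.csv")

spec <- feature_spec("s_RC",
                     auxiliary = c("E_HOMO", "E_LUMO", "E_S1", "E_T1",
                                   "dEST", "f_S1", "dDM"))
dm <- assemble_features(ds$reactions, ds$sensitizers, spec)
cat(sprintf("model matrix: %d rows x %d features\n", nrow(dm$features),
            ncol(dm$features)))

tab <- dplyr::bind_cols(dm$row_ids, dm$features,
                        yield_percent = dm$target)
write_csv(tab, "results/feature_matrix.csv")

# worked example: branching ratios of the first sensitizer
s1 <- scale_rates(as.list(ds$sensitizers[1, c(
  "k_r_S1S0", "k_ic_S1S0", "k_isc_S1T1", "k_risc_T1S1", "k_isc_T1S0")]))
cat("branching ratios of", ds$sensitizers$sensitizer_id[1], ":\n")
print(signif(unclass(s1), 3))
cat("sum:", sum(s1), "\n")
cat("wrote results/feature_matrix.csv\n")
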