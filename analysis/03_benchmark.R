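#!/usr/bin/env Rscript
# Benchmark descriptor sets with 10 repeated random splits: raw log-rates
# (RC), branching ratios (s_RC), s_RC plus electronic descriptors, and
# electronic descriptors alone.

suppressMessages({
  library(photoyield)
  library(readr)
})

ds <- read_dataset("results/data/default_sensitizers.csv",
                   "results/data/default_reactions.csv")

aux4 <- c("E_HOMO", "f_S1", "dEST", "dDM")
specs <- list(
  "RC"            = feature_spec("RC"),
  "s_RC"          = feature_spec("s_RC"),
  "s_RC + aux4"   = feature_spec("s_RC", auxiliary = aux4),
  "aux4 only"     = feature_spec("none", auxiliary = aux4))

rows <- lapply(names(specs), function(nm) {
  dm <- assemble_features(ds$reactions, ds$sensitizers, specs[[nm]])
  ev <- evaluate_repeated(dm, n_runs = 10)
  cat(sprintf("%-14s R2 %.2f (%.2f)   RMSE %5.1f (%.1f)\n", nm,
              ev$mean_r2, ev$sd_r2, ev$mean_rmse, ev$sd_rmse))
  tibble::tibble(descriptor_set = nm, mean_r2 = ev$mean_r2,
                 sd_r2 = ev$sd_r2, mean_rmse = ev$mean_rmse,
                 sd_rmse = ev$sd_rmse)
})
tab <- dplyr::bind_rows(rows)
write_csv(tab, "results/benchmark.csv")
cat("wrote results/benchmark.csv\n")
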