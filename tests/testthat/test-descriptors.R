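test_that("scale_rates reproduces OPS1's reported branching ratios", {
  s <- scale_rates(rate_constant_set(
    k_r_S1S0 = 2.0e7, k_ic_S1S0 = 4.46e4, k_isc_S1T1 = 2.6e7,
    k_risc_T1S1 = 5.3e1, k_isc_T1S0 = 3.6e5))
  expect_lt(abs(s[["s_k_r_S1S0"]] / 0.431 - 1), 0.10)
  expect_lt(abs(s[["s_k_ic_S1S0"]] / 9.6e-4 - 1), 0.10)
  expect_lt(abs(s[["s_k_risc_T1S1"]] / 1.2e-6 - 1), 0.10)
  expect_equal(sum(s), 1)
})

test_that("scale_rates is symmetric, sparse-safe and rejects zero rates", {
  s <- scale_rates(rate_constant_set(3, 3, 3, 3, 3))
  expect_equal(unname(unclass(s)), rep(0.2, 5))
  s0 <- scale_rates(rate_constant_set(1e7, 0, 1e6, 1e2, 1e4))
  expect_identical(s0[["s_k_ic_S1S0"]], 0)
  expect_error(scale_rates(list(k_r_S1S0 = 0, k_ic_S1S0 = 0,
                                k_isc_S1T1 = 0, k_risc_T1S1 = 0,
                                k_isc_T1S0 = 0)))
})

test_that("branching ratios are invariant under overall rate rescaling", {
  set.seed(5)
  for (i in 1:25) {
    k <- 10^runif(5, -3, 9)
    c_pos <- 10^runif(1, -6, 6)
    s1 <- scale_rates(rate_constant_set(k[1], k[2], k[3], k[4], k[5]))
    k2 <- k * c_pos
    s2 <- scale_rates(rate_constant_set(k2[1], k2[2], k2[3], k2[4], k2[5]))
    expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
    # normalization cancels in component ratios
    expect_equal(s1[["s_k_r_S1S0"]] / s1[["s_k_isc_S1T1"]], k[1] / k[3],
                 tolerance = 1e-9)
  }
})

test_that("feature assembly has the expected shape on the 60 x 5 design", {
  d <- default_synthetic()
  dm <- assemble_features(d$reactions, d$sensitizers,
                          feature_spec("s_RC",
                                       auxiliary = c("E_HOMO", "f_S1",
                                                     "dEST", "dDM")))
  expect_equal(dim(dm), c(300L, 5L + 4L + 5L))
  onehot <- as.matrix(dm$features[grep("^reaction_", names(dm$features))])
  expect_true(all(rowSums(onehot) == 1))
  expect_true(all(dm$features[paste0("s_", c(
    "k_r_S1S0", "k_ic_S1S0", "k_isc_S1T1", "k_risc_T1S1",
    "k_isc_T1S0"))] >= 0))
  # deterministic and column-order stable
  dm2 <- assemble_features(d$reactions, d$sensitizers, dm$spec)
  expect_identical(dm$features, dm2$features)
})

test_that("base-set variants control columns and transforms", {
  d <- default_synthetic()
  sub <- d$reactions[d$reactions$reaction_id %in% c("CO-a", "CO-b"), ]
  dm <- assemble_features(sub, d$sensitizers, feature_spec("s_RC"))
  expect_equal(ncol(dm$features), 5L + 2L)

  rc <- assemble_features(sub, d$sensitizers, feature_spec("RC"))
  expect_true(all(grepl("^log10_k_", names(rc$features)[1:5])))
  i <- match(sub$sensitizer_id[1], d$sensitizers$sensitizer_id)
  expect_equal(rc$features$log10_k_r_S1S0[1],
               log10(d$sensitizers$k_r_S1S0[i]))
  raw <- assemble_features(sub, d$sensitizers,
                           feature_spec("RC", rate_transform = "raw"))
  expect_equal(raw$features$k_r_S1S0[1], d$sensitizers$k_r_S1S0[i])
})

test_that("assembly rejects malformed inputs with coordinates", {
  d <- default_synthetic()
  dup <- rbind(d$reactions, d$reactions[1, ])
  expect_error(assemble_features(dup, d$sensitizers, feature_spec("s_RC")),
               "duplicated \\(sensitizer_id, reaction_id\\)")
  orphan <- d$reactions
  orphan$sensitizer_id[3] <- "OPS999"
  expect_error(assemble_features(orphan, d$sensitizers,
                                 feature_spec("s_RC")), "OPS999")
  expect_error(feature_spec("s_RC", auxiliary = "E_HOMO_banana"),
               "unknown auxiliary")
  expect_error(assemble_features(d$reactions, d$sensitizers,
                                 feature_spec("s_RC", extra = "LT_t")),
               "LT_t")
})

test_that("datasets round-trip through CSV exactly", {
  d <- default_synthetic()
  d$sensitizers$LT_t <- 10^runif(nrow(d$sensitizers), -8, -5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(d$sensitizers, d$reactions, dir)
  back <- read_dataset(paths[["sensitizers"]], paths[["reactions"]])
  expect_equal(as.data.frame(back$sensitizers),
               as.data.frame(d$sensitizers))
  expect_equal(as.data.frame(back$reactions), as.data.frame(d$reactions))
  # pass-through lifetime columns land untouched in a lifetime base set
  dm <- assemble_features(back$reactions, back$sensitizers,
                          feature_spec("lifetime"))
  expect_equal(
    dm$features$LT_t,
    back$sensitizers$LT_t[match(back$reactions$sensitizer_id,
                                back$sensitizers$sensitizer_id)])
})

test_that("out-of-range yields and missing columns are rejected", {
  d <- default_synthetic()
  bad <- d$reactions
  bad$yield_percent[17] <- 101
  expect_error(validate <- write_dataset(d$sensitizers, bad,
                                         withr::local_tempdir()),
               "\\[0, 100\\].*17")
  dir <- withr::local_tempdir()
  paths <- write_dataset(d$sensitizers, d$reactions, dir)
  sens <- readr::read_csv(paths[["sensitizers"]], show_col_types = FALSE)
  sens$k_r_S1S0 <- NULL
  readr::write_csv(sens, paths[["sensitizers"]])
  expect_error(read_dataset(paths[["sensitizers"]], paths[["reactions"]]),
               "k_r_S1S0")
})
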