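test_that("a constant model attributes nothing", {
  dm <- toy_problem(n = 30)
  dm$target <- rep(42, 30)
  m <- suppressWarnings(train_model(dm))
  ex <- explain_model(m)
  expect_lt(max(abs(ex$phi)), 1e-9)
  expect_equal(ex$base_value, 42, tolerance = 1e-6)
})

test_that("a single-feature model puts the whole gap on that feature", {
  dm <- toy_problem(n = 80, p = 1, f = function(X) 10 * X[, 1], noise = 0)
  m <- train_model(dm)
  ex <- explain_model(m)
  expect_equal(ex$phi[, 1], ex$prediction - ex$base_value,
               tolerance = 1e-9)
})

test_that("tree attributions equal exact coalition-enumeration values", {
  cases <- list(
    list(n = 40, p = 3, hp = list(nrounds = 20, max_depth = 2), bg = 8),
    list(n = 60, p = 4, hp = list(nrounds = 40, max_depth = 3), bg = 12),
    list(n = 80, p = 6, hp = list(nrounds = 30, max_depth = 4), bg = 16))
  for (cs in cases) {
    dm <- toy_problem(n = cs$n, p = cs$p, seed = cs$p,
                      f = function(X) 5 * X[, 1] + 3 * X[, 2] * X[, 3])
    m <- train_model(dm, cs$hp)
    X <- as.matrix(dm)
    bg <- X[seq_len(cs$bg), , drop = FALSE]
    rows <- X[cs$bg + 1:3, , drop = FALSE]
    ex <- explain_model(m, rows = rows, background = bg)
    pf <- function(H) predict(m, H, precise = TRUE)
    for (i in 1:3) {
      oracle <- exact_shapley(pf, rows[i, ], bg)
      expect_lt(max(abs(ex$phi[i, ] - oracle[colnames(ex$phi)])), 1e-8)
      # additivity of the oracle itself
      expect_equal(sum(oracle) + mean(pf(bg)), pf(rows[i, , drop = FALSE]),
                   tolerance = 1e-10)
    }
  }
})

test_that("additivity holds on every explained row of the synthetic model", {
  d <- default_synthetic()
  dm <- assemble_features(d$reactions, d$sensitizers, full_feature_spec())
  m <- train_model(dm)
  ex <- explain_model(m, background_size = 60)
  expect_lt(max(abs(ex$base_value + rowSums(ex$phi) - ex$prediction)), 1e-6)
  # background subsampling is seed-deterministic
  ex2 <- explain_model(m, background_size = 60)
  expect_identical(ex$phi, ex2$phi)
})

test_that("the exact oracle obeys the additivity and symmetry axioms", {
  set.seed(21)
  bg <- matrix(rnorm(10 * 3), 10)
  colnames(bg) <- c("a", "b", "c")
  x <- c(a = 1.3, b = -0.4, c = 0.8)
  # additive model: attribution of j is g_j(x_j) - mean g_j(background)
  f_add <- function(H) 2 * H[, "a"] - H[, "b"] + 0.5 * H[, "c"]^2
  phi <- exact_shapley(f_add, x, bg)
  expect_equal(phi[["a"]], 2 * x[["a"]] - mean(2 * bg[, "a"]),
               tolerance = 1e-10)
  expect_equal(phi[["b"]], -x[["b"]] + mean(bg[, "b"]), tolerance = 1e-10)
  expect_equal(phi[["c"]], 0.5 * x[["c"]]^2 - mean(0.5 * bg[, "c"]^2),
               tolerance = 1e-10)
  # symmetry: identical duplicated features receive equal attributions
  bg2 <- cbind(bg, d = bg[, "a"])
  x2 <- c(x, d = x[["a"]])
  f_sym <- function(H) H[, "a"] + H[, "d"]
  phi2 <- exact_shapley(f_sym, x2, bg2)
  expect_equal(phi2[["a"]], phi2[["d"]], tolerance = 1e-12)
  expect_error(exact_shapley(f_add, rep(1, 16),
                             matrix(0, 2, 16,
                                    dimnames = list(NULL, paste0("f", 1:16)))),
               "enumeration refused")
})

test_that("attribution summaries rank and order deterministically", {
  dm <- toy_problem(n = 100, f = function(X) 8 * X[, 1] + 0.5 * X[, 2],
                    noise = 0.1)
  m <- train_model(dm)
  ex <- explain_model(m)
  s <- summarize_attributions(ex)
  expect_equal(s$bar$feature[1], "a")  # the dominant driver ranks first
  expect_equal(nrow(s$scatter), 100 * 4)
  expect_equal(s$scatter$value[s$scatter$feature == "a"],
               unname(as.matrix(dm)[, "a"]))
  # ranking is invariant under row permutation
  set.seed(1)
  perm <- sample(100)
  ex_p <- explain_model(m, rows = as.matrix(dm)[perm, ])
  expect_equal(summarize_attributions(ex_p)$bar, s$bar)
  # all-zero attributions rank lexicographically
  zero <- ex
  zero$phi[] <- 0
  expect_equal(summarize_attributions(zero)$bar$feature, letters[1:4])
})

test_that("waterfall tables pool features beyond top_k", {
  expl <- shap_explanation(60, phi = c(a = 5, b = -3, c = 1, d = -0.5),
                           base_value = 57.5)
  wf <- waterfall_table(expl, top_k = 2)
  expect_equal(wf$feature, c("a", "b", "(remaining)"))
  expect_equal(sum(wf$phi), 2.5)
  expect_equal(nrow(waterfall_table(expl)), 4)
})

test_that("pairwise decomposition reproduces the reference worked examples", {
  # C-O coupling (CO-a): OPS1 vs OPS7
  ops1 <- shap_explanation(53.85, phi = c(s_k_risc_T1S1 = -1.17,
                                          s_k_isc_T1S0 = -2.69))
  ops7 <- shap_explanation(85.15, phi = c(s_k_risc_T1S1 = 6.17,
                                          s_k_isc_T1S0 = 8.13))
  pw <- pairwise_attribution(ops1, ops7)
  expect_equal(pw$subset_delta, 18.16, tolerance = 1e-12)
  expect_equal(pw$total_delta, 31.30, tolerance = 1e-12)
  # cyclohexyl radical addition (Cy): OPS1 vs OPS5
  ops1_cy <- shap_explanation(44.11, phi = c(s_k_ic_S1S0 = 0,
                                             s_k_risc_T1S1 = 0,
                                             E_T1 = 3.17))
  ops5_cy <- shap_explanation(2.52, phi = c(s_k_ic_S1S0 = -17.17,
                                            s_k_risc_T1S1 = -11.33,
                                            E_T1 = -4.24))
  pw2 <- pairwise_attribution(ops1_cy, ops5_cy,
                              subset = c("s_k_ic_S1S0", "s_k_risc_T1S1"))
  expect_equal(pw2$subset_delta, -28.50, tolerance = 1e-12)
  expect_equal(pw2$total_delta, -41.59, tolerance = 1e-12)
  expect_equal(abs(pw2$per_feature_delta[["E_T1"]]), 7.41,
               tolerance = 1e-12)
  expect_equal(pw2$subset_share, 28.50 / 41.59, tolerance = 1e-12)
})

test_that("pairwise deltas satisfy the full-subset identity", {
  d <- default_synthetic()
  dm <- assemble_features(d$reactions, d$sensitizers, full_feature_spec())
  m <- train_model(dm)
  ex <- explain_model(m, background_size = 50)
  a <- shap_explanation(ex, 1)
  b <- shap_explanation(ex, 250)
  pw <- pairwise_attribution(a, b)
  expect_equal(sum(pw$per_feature_delta), pw$total_delta, tolerance = 1e-6)
  expect_equal(pw$subset_share, 1, tolerance = 1e-6)
  # identical explanations yield all-zero deltas
  same <- pairwise_attribution(a, a)
  expect_true(all(same$per_feature_delta == 0))
  expect_identical(same$total_delta, 0)
  expect_false(same$undefined)
})
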