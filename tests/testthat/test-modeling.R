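test_that("R2 and RMSE match textbook formulas and definitions", {
  set.seed(9)
  for (i in 1:10) {
    y <- rnorm(50, 50, 20)
    yhat <- y + rnorm(50, 0, 5)
    sse <- sum((y - yhat)^2)
    sst <- sum((y - mean(y))^2)
    expect_equal(r_squared(y, yhat), 1 - sse / sst, tolerance = 1e-12)
    expect_equal(rmse(y, yhat), sqrt(sse / 50), tolerance = 1e-12)
  }
  # a predictor that outputs the test mean scores exactly zero
  y <- rnorm(30)
  expect_equal(r_squared(y, rep(mean(y), 30)), 0)
})

test_that("training is deterministic and interpolates a clean signal", {
  dm <- toy_problem(n = 240, f = function(X) 40 * sin(2 * X[, 1]) + 50,
                    noise = 0)
  m1 <- train_model(dm, seed = 3)
  m2 <- train_model(dm, seed = 3)
  expect_identical(predict(m1), predict(m2))
  expect_gt(r_squared(dm$target, predict(m1)), 0.99)
})

test_that("default synthetic training rows are well fitted", {
  d <- default_synthetic()
  dm <- assemble_features(d$reactions, d$sensitizers, full_feature_spec())
  m <- train_model(dm)
  expect_gte(r_squared(dm$target, predict(m)), 0.9)
})

test_that("degenerate training inputs are handled", {
  dm <- toy_problem(n = 30)
  dm$target <- rep(55, 30)
  expect_warning(m <- train_model(dm), "constant target")
  expect_equal(unname(predict(m)), rep(55, 30), tolerance = 1e-6)
  bad <- toy_problem(n = 30)
  bad$features$a[2] <- Inf
  expect_error(train_model(bad), "non-finite")
  expect_error(train_model(toy_problem(n = 8)), "at least 10 rows")
})

test_that("repeated evaluation aggregates per-run scores with fixed seeds", {
  dm <- toy_problem(n = 120)
  ev <- evaluate_repeated(dm, n_runs = 10, test_fraction = 0.2)
  expect_equal(ev$per_run$seed, 0:9)
  expect_equal(ev$mean_r2, mean(ev$per_run$r2), tolerance = 1e-12)
  expect_equal(ev$mean_rmse, mean(ev$per_run$rmse), tolerance = 1e-12)
  expect_gte(ev$sd_r2, 0)
  # identical seeds give identical splits, hence identical results
  ev2 <- evaluate_repeated(dm, n_runs = 10, test_fraction = 0.2)
  expect_identical(ev$per_run, ev2$per_run)
  expect_error(evaluate_repeated(dm, n_runs = 2, test_fraction = 0.01),
               "fewer than 2 rows")
})

test_that("a noiseless tree-realizable target evaluates near perfectly", {
  dm <- toy_problem(n = 300, p = 4, seed = 2, noise = 0,
                    f = function(X) {
                      30 * (X[, 1] > 0) + 20 * (X[, 2] > 0.5) -
                        25 * (X[, 3] < -0.3) + 10 * (X[, 1] > 1)
                    })
  ev <- evaluate_repeated(dm, n_runs = 5)
  expect_gt(ev$mean_r2, 0.95)
})

test_that("subset enumeration matches a brute-force bitmask oracle", {
  pool <- c("E_HOMO", "f_S1", "dEST")
  subsets <- enumerate_subsets(pool)
  oracle <- lapply(1:7, function(m) pool[as.logical(bitwAnd(m, c(1, 2, 4)))])
  expect_equal(unname(subsets), oracle)
  expect_length(enumerate_subsets(LETTERS[1:7]), 127)
  expect_length(enumerate_subsets("A"), 1)
  expect_length(enumerate_subsets(LETTERS[1:3], include_empty = TRUE), 8)
  expect_error(enumerate_subsets(paste0("x", 1:16)), "guard")
})

test_that("subset search ranks paired evaluations deterministically", {
  d <- default_synthetic()
  res <- subset_search(d$reactions, d$sensitizers,
                       base_sets = c("RC", "s_RC"),
                       auxiliary_pool = c("E_HOMO", "dEST"), n_runs = 2)
  expect_equal(nrow(res), 2 * 3)
  expect_equal(sum(res$base_set == "s_RC"), 3)
  expect_true(all(diff(res$mean_r2) <= 1e-12))
  # identical split seeds across subsets: rerunning reproduces the table
  res2 <- subset_search(d$reactions, d$sensitizers,
                        base_sets = c("RC", "s_RC"),
                        auxiliary_pool = c("E_HOMO", "dEST"), n_runs = 2)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("a pure-noise descriptor changes scores, not bookkeeping", {
  d <- default_synthetic(n_decoys = 1)
  pool <- c("E_HOMO", "dEST")
  res <- subset_search(d$reactions, d$sensitizers, base_sets = "s_RC",
                       auxiliary_pool = pool, n_runs = 2)
  # a decoy column in the sensitizer table is invisible to the search
  expect_equal(nrow(res), 3)
  expect_setequal(res$auxiliary,
                  c("E_HOMO", "dEST", "E_HOMO+dEST"))
})
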