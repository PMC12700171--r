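# Gradient-boosted yield regression: repeated-split evaluation and
# exhaustive descriptor-subset search.

#' Default gradient-boosting hyperparameters
#'
#' Histogram-binned gradient-boosted trees (xgboost `tree_method = "hist"`)
#' with mild shrinkage and depth-4 trees; `subsample = 1` and
#' `colsample_bytree = 1` keep fits fully deterministic. All values can be
#' overridden per call or via the pipeline config.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(nrounds = 100, max_depth = 4, eta = 0.1, min_child_weight = 2,
       subsample = 1, colsample_bytree = 1, lambda = 1)
}

#' Fit a gradient-boosted yield regressor
#'
#' @param dm a [assemble_features()] descriptor matrix (>= 10 rows, no
#'   missing values).
#' @param hyperparams list as in [default_hyperparams()].
#' @param seed integer seed (fits are deterministic for fixed seed).
#' @return Object of class `yield_model`: the fitted booster plus the
#'   feature schema and a reference to the training data (used as the
#'   default attribution background).
#' @export
train_model <- function(dm, hyperparams = default_hyperparams(), seed = 0) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  X <- as.matrix(dm)
  y <- dm$target
  if (nrow(X) < 10) stop("need at least 10 rows to train", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  if (stats::sd(y) == 0) {
    warning("constant target: model will predict the constant",
            call. = FALSE)
  }
  params <- list(objective = "reg:squarederror", tree_method = "hist",
                 max_depth = hp$max_depth, eta = hp$eta,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 lambda = hp$lambda, base_score = mean(y),
                 nthread = 1, seed = seed)
  booster <- with_local_seed(seed, {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = hp$nrounds, verbose = 0)
  })
  structure(list(booster = booster, feature_names = colnames(X),
                 X_train = X, y_train = y, base_score = mean(y),
                 hyperparams = hp, seed = seed),
            class = "yield_model")
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("<yield_model> %d features, %d training rows, %d rounds\n",
              length(x$feature_names), nrow(x$X_train),
              x$hyperparams$nrounds))
  invisible(x)
}

# coerce prediction input to a feature matrix matching the model schema
model_matrix_for <- function(model, newdata) {
  if (inherits(newdata, "descriptor_matrix")) newdata <- as.matrix(newdata)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(model$feature_names)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(model$feature_names), call. = FALSE)
    }
    colnames(newdata) <- model$feature_names
  }
  missing_cols <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata is missing model feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  newdata[, model$feature_names, drop = FALSE]
}

#' Predict yields from a fitted model
#'
#' @param object a [train_model()] fit.
#' @param newdata descriptor matrix, numeric matrix or data frame
#'   (defaults to the training rows).
#' @param precise evaluate the trees in double precision instead of the
#'   booster's native float32 accumulation. The difference is below 1e-4
#'   yield points; the attribution module uses the precise path so that
#'   additivity holds to numerical precision.
#' @param ... unused.
#' @export
predict.yield_model <- function(object, newdata = NULL, precise = FALSE,
                                ...) {
  if (is.null(newdata)) newdata <- object$X_train
  X <- model_matrix_for(object, newdata)
  if (precise) {
    arr <- model_tree_arrays(object)
    object$base_score +
      tree_predict_cpp(arr$tree_root, arr$feature, arr$threshold,
                       arr$yes, arr$no, arr$value, X)
  } else {
    stats::predict(object$booster, X)
  }
}

#' Coefficient of determination on a held-out set
#'
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2} with \eqn{\bar y}
#' the mean of `y` itself (i.e. of the test fold when scoring a split).
#' @param y observed values. @param yhat predictions.
#' @export
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Root-mean-square error
#' @param y observed values. @param yhat predictions.
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Repeated random-split evaluation
#'
#' For run i (seed `split_seeds[i]`): draw a uniform random test split,
#' fit on the remainder, and score \eqn{R^2} and RMSE on the test rows;
#' report per-run scores plus their mean and sample standard deviation.
#' Fixed seeds 0..n_runs-1 make subset comparisons paired: every feature
#' subset sees the identical sequence of splits.
#'
#' @param dm descriptor matrix.
#' @param n_runs number of random splits.
#' @param test_fraction held-out fraction in (0, 1).
#' @param hyperparams see [default_hyperparams()].
#' @param split_seeds integer vector of length `n_runs`.
#' @return Object of class `evaluation_result` with `mean_r2`, `sd_r2`,
#'   `mean_rmse`, `sd_rmse`, a `per_run` tibble and the feature `spec`.
#' @export
evaluate_repeated <- function(dm, n_runs = 10, test_fraction = 0.2,
                              hyperparams = default_hyperparams(),
                              split_seeds = seq_len(n_runs) - 1L) {
  stopifnot(inherits(dm, "descriptor_matrix"), n_runs >= 1,
            test_fraction > 0, test_fraction < 1,
            length(split_seeds) == n_runs)
  n <- nrow(dm$features)
  n_test <- round(n * test_fraction)
  if (n_test < 2) stop("test split would have fewer than 2 rows",
                       call. = FALSE)
  runs <- lapply(split_seeds, function(seed) {
    test_idx <- with_local_seed(seed, sample.int(n, n_test))
    fit <- train_model(dm_subset(dm, -test_idx), hyperparams, seed = seed)
    yhat <- predict(fit, dm_subset(dm, test_idx))
    y <- dm$target[test_idx]
    tibble::tibble(seed = seed, r2 = r_squared(y, yhat),
                   rmse = rmse(y, yhat))
  })
  per_run <- dplyr::bind_rows(runs)
  structure(list(mean_r2 = mean(per_run$r2),
                 sd_r2 = stats::sd(per_run$r2),
                 mean_rmse = mean(per_run$rmse),
                 sd_rmse = stats::sd(per_run$rmse),
                 per_run = per_run, spec = dm$spec),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s\n  R2 %.3f (%.3f)  RMSE %.2f (%.2f)  [%d runs]\n",
              feature_spec_label(x$spec), x$mean_r2, x$sd_r2,
              x$mean_rmse, x$sd_rmse, nrow(x$per_run)))
  invisible(x)
}

#' Enumerate auxiliary-descriptor subsets
#'
#' All non-empty subsets of the descriptor pool, in bitmask order
#' (deterministic). A pool of d descriptors yields 2^d - 1 subsets.
#'
#' @param pool character vector of descriptor names (d <= 15).
#' @param include_empty also return the empty subset first.
#' @return List of character vectors, named by their `+`-joined label.
#' @export
enumerate_subsets <- function(pool, include_empty = FALSE) {
  d <- length(pool)
  if (d > 15) {
    stop("pool of ", d, " descriptors exceeds the exhaustive-enumeration ",
         "guard (15); a heuristic search mode is not implemented",
         call. = FALSE)
  }
  masks <- if (include_empty) 0:(2^d - 1) else seq_len(2^d - 1)
  subsets <- lapply(masks, function(m) pool[bitwAnd(m, 2^(seq_len(d) - 1)) > 0])
  names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  if (include_empty) names(subsets)[1] <- "(none)"
  subsets
}

#' Exhaustive descriptor-subset search
#'
#' Evaluates every non-empty subset of the auxiliary pool combined with
#' each base rate-constant set, using identical split seeds across subsets
#' so comparisons are paired, and returns the ranked table (mean R2
#' descending; ties by mean RMSE ascending, then by subset label).
#'
#' @param reactions,sensitizers the dataset tables.
#' @param base_sets character vector of base sets (e.g. `c("RC","s_RC")`;
#'   `"none"` gives auxiliary-only entries).
#' @param auxiliary_pool auxiliary descriptor pool (d <= 15).
#' @param n_runs,test_fraction,hyperparams passed to [evaluate_repeated()].
#' @param include_base_only also evaluate each base set with no auxiliaries.
#' @param include_reaction_onehot,rate_transform passed to [feature_spec()].
#' @return Object of class `search_result`: a tibble with columns
#'   `base_set`, `auxiliary`, `n_aux`, `mean_r2`, `sd_r2`, `mean_rmse`,
#'   `sd_rmse`, plus the evaluated specs in `attr(, "specs")`.
#' @export
subset_search <- function(reactions, sensitizers, base_sets = "s_RC",
                          auxiliary_pool = AUX_NAMES, n_runs = 3,
                          test_fraction = 0.2,
                          hyperparams = default_hyperparams(),
                          include_base_only = FALSE,
                          include_reaction_onehot = TRUE,
                          rate_transform = "log10") {
  subsets <- enumerate_subsets(auxiliary_pool,
                               include_empty = include_base_only)
  grid <- expand.grid(base = base_sets, subset = seq_along(subsets),
                      stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    feature_spec(base_set = grid$base[i],
                 auxiliary = subsets[[grid$subset[i]]],
                 include_reaction_onehot = include_reaction_onehot,
                 rate_transform = rate_transform)
  })
  rows <- lapply(seq_along(specs), function(i) {
    dm <- assemble_features(reactions, sensitizers, specs[[i]])
    ev <- evaluate_repeated(dm, n_runs = n_runs,
                            test_fraction = test_fraction,
                            hyperparams = hyperparams)
    tibble::tibble(base_set = grid$base[i],
                   auxiliary = names(subsets)[grid$subset[i]],
                   n_aux = length(subsets[[grid$subset[i]]]),
                   mean_r2 = ev$mean_r2, sd_r2 = ev$sd_r2,
                   mean_rmse = ev$mean_rmse, sd_rmse = ev$sd_rmse)
  })
  tab <- dplyr::bind_rows(rows)
  ord <- order(-tab$mean_r2, tab$mean_rmse, tab$auxiliary)
  tab <- tab[ord, ]
  structure(tab, specs = specs[ord], class = c("search_result",
                                               class(tab)))
}
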