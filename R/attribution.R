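# Shapley-value attribution for the fitted tree ensembles:
# interventional tree-Shapley (compiled), an exact coalition-enumeration
# oracle, summary/scatter/waterfall data products, and pairwise
# predicted-yield difference decomposition.

# parse the fitted booster into flat node arrays for the C++ walker
model_tree_arrays <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model$booster)
  dt <- as.data.frame(dt)
  idx <- stats::setNames(seq_len(nrow(dt)) - 1L, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  feat <- match(dt$Feature, model$feature_names) - 1L
  feat[is_leaf] <- -1L
  if (any(is.na(feat) & !is_leaf)) {
    stop("tree dump references unknown feature(s)", call. = FALSE)
  }
  list(tree_root = unname(idx[dt$ID[dt$Node == 0]]),
       feature = as.integer(feat),
       threshold = ifelse(is_leaf, 0, dt$Split),
       yes = as.integer(ifelse(is_leaf, -1L, idx[dt$Yes])),
       no = as.integer(ifelse(is_leaf, -1L, idx[dt$No])),
       value = ifelse(is_leaf, dt$Gain, 0))
}

#' Shapley attributions for model predictions
#'
#' Computes per-feature additive attributions of each prediction relative
#' to the expected model output over a background set, using exact
#' interventional feature perturbation: absent features are replaced by
#' background-row values and the resulting coalition game is solved in
#' closed form per tree leaf (averaged over the background). For every
#' explained row, `base_value + sum(phi) = prediction` holds to numerical
#' precision.
#'
#' @param model a [train_model()] fit.
#' @param rows rows to explain (descriptor matrix or numeric matrix);
#'   defaults to the training data.
#' @param background background rows; defaults to the full training data.
#' @param background_size optional subsample size for the background
#'   (drawn with `seed`).
#' @param seed seed for the background subsample.
#' @return Object of class `shap_explanations`: `base_value`, matrix `phi`
#'   (rows x features), `prediction`, `feature_values`, `feature_names`,
#'   `row_ids`.
#' @export
explain_model <- function(model, rows = NULL, background = NULL,
                          background_size = NULL, seed = 0) {
  stopifnot(inherits(model, "yield_model"))
  row_ids <- NULL
  if (inherits(rows, "descriptor_matrix")) {
    row_ids <- rows$row_ids
  }
  X <- model_matrix_for(model, if (is.null(rows)) model$X_train else rows)
  R <- model_matrix_for(model,
                        if (is.null(background)) model$X_train else background)
  if (nrow(R) == 0) stop("background must be non-empty", call. = FALSE)
  if (!is.null(background_size) && background_size < nrow(R)) {
    keep <- with_local_seed(seed, sample.int(nrow(R), background_size))
    R <- R[keep, , drop = FALSE]
  }
  arr <- model_tree_arrays(model)
  phi <- treeshap_interventional_cpp(arr$tree_root, arr$feature,
                                     arr$threshold, arr$yes, arr$no,
                                     arr$value, X, R)
  colnames(phi) <- model$feature_names
  margin <- function(M) model$base_score +
    tree_predict_cpp(arr$tree_root, arr$feature, arr$threshold, arr$yes,
                     arr$no, arr$value, M)
  structure(list(base_value = mean(margin(R)),
                 phi = phi,
                 prediction = margin(X),
                 feature_values = X,
                 feature_names = model$feature_names,
                 row_ids = row_ids),
            class = "shap_explanations")
}

#' @export
print.shap_explanations <- function(x, ...) {
  cat(sprintf("<shap_explanations> %d rows x %d features, base value %.3f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' Single-row explanation
#'
#' Either extracts row `i` of a [explain_model()] result, or constructs an
#' explanation directly from a prediction and per-feature attributions
#' (useful for arithmetic on attributions reported elsewhere; when
#' `base_value` is omitted the explanation is marked partial and the
#' additivity check is skipped).
#'
#' @param x a `shap_explanations` object, or a numeric prediction.
#' @param i row index (when extracting).
#' @param phi named numeric vector of attributions (when constructing).
#' @param base_value expected model output over the background.
#' @return Object of class `shap_explanation` with `base_value`, `phi`,
#'   `prediction`.
#' @export
shap_explanation <- function(x, i = NULL, phi = NULL, base_value = NULL) {
  if (inherits(x, "shap_explanations")) {
    stopifnot(!is.null(i), i >= 1, i <= nrow(x$phi))
    return(structure(list(base_value = x$base_value,
                          phi = x$phi[i, ],
                          prediction = x$prediction[i], partial = FALSE),
                     class = "shap_explanation"))
  }
  prediction <- as.numeric(x)
  stopifnot(is.numeric(phi), !is.null(names(phi)))
  partial <- is.null(base_value)
  if (!partial &&
      abs(base_value + sum(phi) - prediction) > 1e-6) {
    stop("additivity violated: base_value + sum(phi) != prediction",
         call. = FALSE)
  }
  structure(list(base_value = if (partial) NA_real_ else base_value,
                 phi = phi, prediction = prediction, partial = partial),
            class = "shap_explanation")
}

#' Exact Shapley values by coalition enumeration
#'
#' Independent brute-force oracle: for every coalition S of features, the
#' value is the mean over background rows of the model prediction with
#' features outside S replaced by the background values; attributions are
#' the classic Shapley sum over all 2^d coalitions. Tractable up to ~15
#' features.
#'
#' @param predict_fun function taking a numeric feature matrix and
#'   returning predictions.
#' @param row named numeric vector (the row to explain).
#' @param background numeric matrix with the same columns.
#' @param features feature names to attribute over (default: all columns).
#' @return Named numeric vector of attributions.
#' @export
exact_shapley <- function(predict_fun, row, background,
                          features = colnames(background)) {
  row <- unlist(row)
  background <- as.matrix(background)
  if (is.null(colnames(background))) colnames(background) <- names(row)
  d <- length(features)
  if (d > 15) stop("more than 15 features: enumeration refused",
                   call. = FALSE)
  nb <- nrow(background)
  v <- numeric(2^d)
  for (mask in 0:(2^d - 1)) {
    H <- background
    in_S <- features[bitwAnd(mask, 2^(seq_len(d) - 1)) > 0]
    for (f in in_S) H[, f] <- row[[f]]
    v[mask + 1] <- mean(predict_fun(H))
  }
  w <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  phi <- stats::setNames(numeric(d), features)
  for (i in seq_len(d)) {
    bit <- 2^(i - 1)
    for (mask in 0:(2^d - 1)) {
      if (bitwAnd(mask, bit) == 0) {
        s <- sum(bitwAnd(mask, 2^(seq_len(d) - 1)) > 0)
        phi[i] <- phi[i] + w[s + 1] * (v[mask + bit + 1] - v[mask + 1])
      }
    }
  }
  phi
}

#' Summarize attributions across rows
#'
#' Produces the data behind the standard attribution displays: the global
#' importance ranking (mean absolute attribution per feature, ties broken
#' lexicographically) and the per-row (feature value, attribution) pairs
#' for scatter/summary plots, in input row order.
#'
#' @param explanations a [explain_model()] result.
#' @return List with tibbles `bar` (`feature`, `mean_abs_phi`, ranked) and
#'   `scatter` (`row`, `feature`, `value`, `phi`).
#' @export
summarize_attributions <- function(explanations) {
  stopifnot(inherits(explanations, "shap_explanations"))
  m <- colMeans(abs(explanations$phi))
  bar <- tibble::tibble(feature = names(m), mean_abs_phi = unname(m))
  bar <- bar[order(-bar$mean_abs_phi, bar$feature), ]
  nf <- ncol(explanations$phi)
  nr <- nrow(explanations$phi)
  scatter <- tibble::tibble(
    row = rep(seq_len(nr), times = nf),
    feature = rep(colnames(explanations$phi), each = nr),
    value = as.vector(explanations$feature_values[,
      colnames(explanations$phi), drop = FALSE]),
    phi = as.vector(explanations$phi))
  list(bar = bar, scatter = scatter)
}

#' Waterfall table for one explanation
#'
#' Features ordered by decreasing absolute attribution; below `top_k` the
#' remainder is pooled into a single `"(remaining)"` bucket.
#'
#' @param explanation a [shap_explanation()].
#' @param top_k number of features shown individually.
#' @return Tibble with columns `feature`, `phi`.
#' @export
waterfall_table <- function(explanation, top_k = Inf) {
  stopifnot(inherits(explanation, "shap_explanation"))
  phi <- explanation$phi
  ord <- order(-abs(phi), names(phi))
  phi <- phi[ord]
  if (is.finite(top_k) && top_k < length(phi)) {
    out <- tibble::tibble(feature = names(phi)[seq_len(top_k)],
                          phi = unname(phi[seq_len(top_k)]))
    out <- dplyr::bind_rows(out, tibble::tibble(
      feature = "(remaining)", phi = sum(phi[-seq_len(top_k)])))
  } else {
    out <- tibble::tibble(feature = names(phi), phi = unname(phi))
  }
  out
}

#' Decompose a pairwise predicted-yield difference
#'
#' For two explanations from the same model and background, the base
#' values cancel and the difference of predictions decomposes additively
#' into per-feature attribution differences. The share of a named feature
#' subset quantifies how much of the predicted-yield gap those descriptors
#' account for (e.g. "18.16 of a 31.30 yield-point difference").
#'
#' @param expl_A,expl_B [shap_explanation()] objects sharing the feature
#'   schema (and base value, when known).
#' @param subset feature names to aggregate (default: all shared features).
#' @return Object of class `pairwise_attribution`: `total_delta`
#'   (`prediction_B - prediction_A`), `per_feature_delta`, `subset_delta`,
#'   `subset_share` (`subset_delta / total_delta`; `NA` and flagged
#'   `undefined` when `total_delta` is 0), and `subset_share_abs`
#'   (`subset_delta / |total_delta|`).
#' @export
pairwise_attribution <- function(expl_A, expl_B,
                                 subset = names(expl_A$phi)) {
  stopifnot(inherits(expl_A, "shap_explanation"),
            inherits(expl_B, "shap_explanation"))
  if (!setequal(names(expl_A$phi), names(expl_B$phi))) {
    stop("explanations do not share a feature schema", call. = FALSE)
  }
  if (!is.na(expl_A$base_value) && !is.na(expl_B$base_value) &&
      abs(expl_A$base_value - expl_B$base_value) > 1e-6) {
    stop("explanations have different base values: compare explanations ",
         "from the same model and background", call. = FALSE)
  }
  bad <- setdiff(subset, names(expl_A$phi))
  if (length(bad) > 0) {
    stop("subset names not among the features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  delta <- expl_B$phi[names(expl_A$phi)] - expl_A$phi
  total <- expl_B$prediction - expl_A$prediction
  subset_delta <- sum(delta[subset])
  undefined <- total == 0 && subset_delta != 0
  structure(list(total_delta = total, per_feature_delta = delta,
                 subset = subset, subset_delta = subset_delta,
                 subset_share = if (total == 0) NA_real_ else
                   subset_delta / total,
                 subset_share_abs = if (total == 0) NA_real_ else
                   subset_delta / abs(total),
                 undefined = undefined),
            class = "pairwise_attribution")
}

#' @export
print.pairwise_attribution <- function(x, ...) {
  cat(sprintf("<pairwise_attribution> delta(prediction) = %.2f\n",
              x$total_delta))
  cat(sprintf("  subset {%s}: %.2f yield points",
              paste(x$subset, collapse = ", "), x$subset_delta))
  if (x$undefined) {
    cat("  (share undefined: zero total difference)\n")
  } else if (!is.na(x$subset_share)) {
    cat(sprintf(" = %.1f%% of the difference\n", 100 * x$subset_share))
  } else cat("\n")
  invisible(x)
}
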