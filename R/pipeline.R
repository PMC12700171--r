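# End-to-end orchestration: config validation and the full analysis
# pipeline (simulate/load -> assemble -> evaluate or search -> train ->
# attribute -> report). All outputs are delimited text plus one JSON
# manifest; identical config and seeds give identical numeric outputs.

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Exactly one data source must
#' be configured: a `dataset` block (`sensitizers`/`reactions` CSV paths)
#' or a `simulate` block ([generator_config()] arguments); an empty config
#' simulates with defaults. Optional blocks: `features`
#' ([feature_spec()] arguments), `search` (`base_sets`, `auxiliary_pool`,
#' `n_runs`), `evaluation` (`n_runs`, `test_fraction`, `hyperparams`),
#' `attribution` (`background_size`, `pairs`: each with `a`, `b` as
#' `(sensitizer_id, reaction_id)` and an optional feature `subset`),
#' `output_dir`, `seed`. All errors are collected and reported together;
#' a bad config is never partially applied.
#'
#' @param config path to a YAML file, or a list.
#' @return Normalized list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  known <- c("dataset", "simulate", "features", "search", "evaluation",
             "attribution", "output_dir", "seed")
  for (nm in setdiff(names(config), known)) {
    note(paste0("unknown config block: ", nm))
  }
  if (!is.null(config$dataset) && !is.null(config$simulate)) {
    note("config must contain at most one of 'dataset' and 'simulate'")
  }
  if (!is.null(config$dataset)) {
    for (nm in c("sensitizers", "reactions")) {
      if (is.null(config$dataset[[nm]])) {
        note(paste0("dataset.", nm, ": path is required"))
      }
    }
  }
  simulate_cfg <- NULL
  if (is.null(config$dataset)) {
    simulate_cfg <- tryCatch(
      do.call(generator_config, config$simulate %||% list()),
      error = function(e) {
        note(paste0("simulate: ", conditionMessage(e)))
        NULL
      })
  }
  features <- tryCatch(
    do.call(feature_spec, utils::modifyList(
      list(base_set = "s_RC", auxiliary = AUX_NAMES),
      config$features %||% list())),
    error = function(e) {
      note(paste0("features: ", conditionMessage(e)))
      NULL
    })
  search <- NULL
  if (!is.null(config$search)) {
    search <- utils::modifyList(
      list(base_sets = "s_RC", auxiliary_pool = AUX_NAMES, n_runs = 3),
      config$search)
    bad <- setdiff(search$auxiliary_pool, AUX_NAMES)
    if (length(bad) > 0) {
      note(paste0("search.auxiliary_pool: unknown descriptor(s) ",
                  paste(bad, collapse = ", ")))
    }
    if (length(search$auxiliary_pool) > 15) {
      note("search.auxiliary_pool: more than 15 descriptors")
    }
  }
  evaluation <- utils::modifyList(
    list(n_runs = 10, test_fraction = 0.2,
         hyperparams = default_hyperparams()),
    config$evaluation %||% list())
  if (evaluation$test_fraction <= 0 || evaluation$test_fraction >= 1) {
    note("evaluation.test_fraction must be in (0, 1)")
  }
  # note: modifyList would recurse into (and drop) the unnamed pairs list
  attribution <- list(
    background_size = config$attribution$background_size,
    pairs = config$attribution$pairs %||% list())
  for (i in seq_along(attribution$pairs)) {
    p <- attribution$pairs[[i]]
    for (side in c("a", "b")) {
      if (length(p[[side]]) != 2) {
        note(sprintf(
          "attribution.pairs[%d].%s must be (sensitizer_id, reaction_id)",
          i, side))
      }
    }
    bad <- setdiff(p$subset %||% character(),
                   c(AUX_NAMES, SCALED_NAMES, RATE_NAMES,
                     paste0("log10_", RATE_NAMES)))
    if (length(bad) > 0 && !all(grepl("^(reaction_|decoy_|LT_)", bad))) {
      note(sprintf("attribution.pairs[%d].subset: unknown feature(s) %s",
                   i, paste(bad, collapse = ", ")))
    }
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(dataset = config$dataset, simulate = simulate_cfg,
                 features = features, search = search,
                 evaluation = evaluation, attribution = attribution,
                 output_dir = config$output_dir %||% "results",
                 seed = config$seed %||% 0L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(x, dir, name) {
  readr::write_csv(x, file.path(dir, name), progress = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, feature assembly, repeated-split evaluation
#' (or the exhaustive subset search when a `search` block is configured),
#' trains the final model on all rows, computes Shapley attributions for
#' every row, and writes all tables (dataset, evaluation/search,
#' attribution bar/scatter/per-row tables, waterfall and pairwise reports)
#' plus a machine-readable JSON manifest and a human-readable summary
#' under the configured output directory.
#'
#' @param config a [validate_config()] result, YAML path, or list.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the dataset, descriptor matrix,
#'   evaluation/search results, model, explanations and pairwise reports.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(config$simulate)) {
    say("stage simulate: ", config$simulate$n_sensitizers, " sensitizers x ",
        length(config$simulate$reaction_ids), " reactions")
    sens <- generate_sensitizers(config$simulate)
    reactions <- generate_yields(sens, config$simulate)
    write_dataset(sens, reactions, out_dir, prefix = "synthetic")
  } else {
    say("stage load: ", config$dataset$sensitizers)
    ds <- read_dataset(config$dataset$sensitizers, config$dataset$reactions)
    sens <- ds$sensitizers
    reactions <- ds$reactions
  }

  say("stage assemble: ", feature_spec_label(config$features))
  dm <- assemble_features(reactions, sens, config$features)

  search_result <- NULL
  if (!is.null(config$search)) {
    say("stage search: ", length(config$search$base_sets), " base set(s) x ",
        2^length(config$search$auxiliary_pool) - 1, " subsets")
    search_result <- subset_search(
      reactions, sens, base_sets = config$search$base_sets,
      auxiliary_pool = config$search$auxiliary_pool,
      n_runs = config$search$n_runs,
      test_fraction = config$evaluation$test_fraction,
      hyperparams = config$evaluation$hyperparams)
    write_table(tibble::as_tibble(search_result), out_dir, "search.csv")
    best_spec <- attr(search_result, "specs")[[1]]
    say("  best: ", feature_spec_label(best_spec))
    dm <- assemble_features(reactions, sens, best_spec)
  }

  say("stage evaluate: ", config$evaluation$n_runs, " runs")
  evaluation <- evaluate_repeated(
    dm, n_runs = config$evaluation$n_runs,
    test_fraction = config$evaluation$test_fraction,
    hyperparams = config$evaluation$hyperparams)
  say(sprintf("  mean R2 %.3f (sd %.3f), mean RMSE %.2f (sd %.2f)",
              evaluation$mean_r2, evaluation$sd_r2, evaluation$mean_rmse,
              evaluation$sd_rmse))
  write_table(evaluation$per_run, out_dir, "evaluation_runs.csv")

  say("stage train: final model on all rows")
  model <- train_model(dm, config$evaluation$hyperparams, seed = config$seed)

  say("stage explain: ", nrow(dm$features), " rows")
  expl <- explain_model(model, rows = dm,
                        background_size = config$attribution$background_size,
                        seed = config$seed)
  summaries <- summarize_attributions(expl)
  write_table(summaries$bar, out_dir, "attribution_bar.csv")
  write_table(summaries$scatter, out_dir, "attribution_scatter.csv")
  phi_long <- tibble::tibble(
    sensitizer_id = rep(expl$row_ids$sensitizer_id, ncol(expl$phi)),
    reaction_id = rep(expl$row_ids$reaction_id, ncol(expl$phi)),
    feature = rep(colnames(expl$phi), each = nrow(expl$phi)),
    phi = as.vector(expl$phi))
  write_table(phi_long, out_dir, "attribution_rows.csv")

  pairwise <- list()
  if (length(config$attribution$pairs) > 0) {
    say("stage compare: ", length(config$attribution$pairs), " pair(s)")
    find_row <- function(key) {
      i <- which(expl$row_ids$sensitizer_id == key[[1]] &
                 expl$row_ids$reaction_id == key[[2]])
      if (length(i) != 1) {
        stop("pairwise comparison references unknown row (",
             key[[1]], ", ", key[[2]], ")", call. = FALSE)
      }
      i
    }
    pairwise_rows <- lapply(config$attribution$pairs, function(p) {
      ia <- find_row(p$a); ib <- find_row(p$b)
      subset <- p$subset %||% expl$feature_names
      pw <- pairwise_attribution(shap_explanation(expl, ia),
                                 shap_explanation(expl, ib),
                                 subset = subset)
      tibble::tibble(
        a = paste(p$a, collapse = "|"), b = paste(p$b, collapse = "|"),
        subset = paste(subset, collapse = "+"),
        subset_delta = pw$subset_delta, total_delta = pw$total_delta,
        subset_share = pw$subset_share)
    })
    pairwise <- dplyr::bind_rows(pairwise_rows)
    write_table(pairwise, out_dir, "pairwise.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("photoyield")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_rows = nrow(dm$features),
    features = colnames(dm$features),
    evaluation = list(mean_r2 = evaluation$mean_r2,
                      sd_r2 = evaluation$sd_r2,
                      mean_rmse = evaluation$mean_rmse,
                      sd_rmse = evaluation$sd_rmse))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("photoyield pipeline summary"),
    sprintf("rows: %d  features: %d (%s)", nrow(dm$features),
            ncol(dm$features), feature_spec_label(dm$spec)),
    sprintf("mean test R2: %.3f (sd %.3f) over %d runs",
            evaluation$mean_r2, evaluation$sd_r2,
            nrow(evaluation$per_run)),
    sprintf("mean test RMSE: %.2f (sd %.2f) yield points",
            evaluation$mean_rmse, evaluation$sd_rmse),
    sprintf("top features by mean |phi|: %s",
            paste(utils::head(summaries$bar$feature, 5), collapse = ", "))),
    file.path(out_dir, "summary.txt"))

  invisible(list(sensitizers = sens, reactions = reactions, matrix = dm,
                 search = search_result, evaluation = evaluation,
                 model = model, explanations = expl,
                 summaries = summaries, pairwise = pairwise,
                 manifest = manifest))
}
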