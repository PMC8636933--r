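# End-to-end orchestration: preprocess -> Kennard-Stone split ->
# (optional) hyperparameter search -> base-classifier population ->
# selection -> model-level representation -> meta-classifier -> evaluation.
# run_pipeline() is the programmatic surface; when out_dir is given every
# intermediate artifact is written as plain text so a run is re-derivable
# from its stored configuration.

#' Pipeline run configuration
#'
#' @param split_sizes Integer vector `c(n_train, n_dev, n_test)`.
#' @param algorithms Base algorithms to use (default all five).
#' @param grids Named list of hyperparameter grids per algorithm; a grid
#'   with a single combination skips comparison and uses it directly.
#'   Defaults to [default_grids()].
#' @param n_search_models Classifiers per combination during the search
#'   (default 100); `0` disables the search and takes each grid's first
#'   combination.
#' @param n_population_models Classifiers per algorithm in the final
#'   population (default 1000).
#' @param selection `"supervised"` or `"original"`.
#' @param subsample_frac Training-row fraction per subsample (0.8).
#' @param meta Named list of overrides for [meta_config()] (e.g. `epochs`).
#' @param threshold Decision threshold for evaluation (0.5).
#' @param seed Master integer seed; every stochastic stage derives its own
#'   seed from it.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(split_sizes, algorithms = BASE_ALGORITHMS,
                       grids = default_grids(), n_search_models = 100L,
                       n_population_models = 1000L,
                       selection = c("supervised", "original"),
                       subsample_frac = 0.8, meta = list(),
                       threshold = 0.5, seed = NULL) {
  selection <- match.arg(selection)
  if (is.null(seed)) stop("config must declare a seed before any compute")
  algorithms <- match.arg(algorithms, BASE_ALGORITHMS, several.ok = TRUE)
  missing_grids <- setdiff(algorithms, names(grids))
  if (length(missing_grids)) {
    stop("no hyperparameter grid for: ", paste(missing_grids, collapse = ", "))
  }
  structure(list(split_sizes = as.integer(split_sizes),
                 algorithms = algorithms, grids = grids,
                 n_search_models = as.integer(n_search_models),
                 n_population_models = as.integer(n_population_models),
                 selection = selection, subsample_frac = subsample_frac,
                 meta = meta, threshold = threshold, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full stacked-ensemble pipeline
#'
#' Takes a preprocessed descriptor matrix with labels, splits it by
#' sequential Kennard-Stone sampling, trains and selects base classifiers,
#' builds the development-set model-level representation, trains the
#' neural meta-classifier on it, and evaluates on the development and test
#' sets. With `out_dir` set, writes the split CSV, the per-member manifest
#' JSON, prediction CSVs, a metrics JSON and a threshold-prioritization
#' CSV.
#'
#' @param m A preprocessed [descriptor_matrix()].
#' @param labels Binary 0/1 labels aligned with `m`'s rows.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `PipelineResult`: `split`, `best_combos`,
#'   `population`, `ensemble`, `meta_model`, `mlr_dev`, per-set
#'   probabilities, `metrics` (dev and test `MetricsBundle`s),
#'   `base_mean_dev_mcc`, `prioritization` (test-set threshold table) and
#'   the `config`.
#' @export
run_pipeline <- function(m, labels, config, out_dir = NULL) {
  stopifnot(inherits(m, "DescriptorMatrix"), inherits(config, "RunConfig"))
  if (length(labels) != nrow(m$values)) stop("labels do not align with descriptors")
  names(labels) <- m$compound_ids

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  split <- stage("split", three_way_split(m, config$split_sizes))
  train_x <- m$values[split$train_ids, , drop = FALSE]
  dev_x <- m$values[split$dev_ids, , drop = FALSE]
  test_x <- m$values[split$test_ids, , drop = FALSE]
  train_y <- labels[split$train_ids]
  dev_y <- labels[split$dev_ids]
  test_y <- labels[split$test_ids]

  best_combos <- list()
  population <- list()
  for (ai in seq_along(config$algorithms)) {
    alg <- config$algorithms[ai]
    alg_seed <- config$seed + 10000L * ai
    grid <- config$grids[[alg]]
    combos <- expand_grid_combos(grid)
    best <- if (config$n_search_models > 0L && nrow(combos) > 1L) {
      stage(paste0("search_", alg),
            bootstrap_hyperparameter_search(
              alg, grid, train_x, train_y, dev_x, dev_y,
              n_models = config$n_search_models,
              subsample_frac = config$subsample_frac,
              seed = alg_seed))$best
    } else {
      as.list(combos[1L, , drop = FALSE])
    }
    best_combos[[alg]] <- best
    population <- c(population, stage(
      paste0("population_", alg),
      train_base_population(alg, best, train_x, train_y, dev_x, dev_y,
                            n_models = config$n_population_models,
                            subsample_frac = config$subsample_frac,
                            seed = alg_seed + 5000L)))
  }

  ensemble <- stage("select", switch(config$selection,
                                     supervised = select_supervised(population),
                                     original = select_original(population)))
  mlr_dev <- stage("mlr_dev", predict_probabilities(ensemble, dev_x))
  meta_args <- utils::modifyList(
    list(input_dim = ncol(mlr_dev$probs), seed = config$seed + 777L),
    config$meta)
  meta <- stage("train_meta",
                train_meta(do.call(meta_config, meta_args), mlr_dev, dev_y))

  dev_probs <- predict_meta(meta, mlr_dev)
  mlr_test <- stage("mlr_test", predict_probabilities(ensemble, test_x))
  test_probs <- predict_meta(meta, mlr_test)

  base_mean_dev_mcc <- mean(vapply(ensemble$members, `[[`, numeric(1), "mcc_dev"))
  metrics <- list(dev = evaluate_predictions(dev_probs, dev_y, config$threshold),
                  test = evaluate_predictions(test_probs, test_y, config$threshold))
  prioritization <- threshold_prioritization(test_probs, test_y)

  result <- structure(
    list(split = split, best_combos = best_combos, population = population,
         ensemble = ensemble, meta_model = meta, mlr_dev = mlr_dev,
         dev_probs = dev_probs, test_probs = test_probs,
         dev_labels = dev_y, test_labels = test_y,
         metrics = metrics, base_mean_dev_mcc = base_mean_dev_mcc,
         prioritization = prioritization, config = config),
    class = "PipelineResult")
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("<PipelineResult> ", length(x$ensemble$members),
      " selected base classifiers (", x$config$selection, ")\n", sep = "")
  cat("  dev  MCC ", sprintf("%.3f", x$metrics$dev$mcc),
      " (base-member mean ", sprintf("%.3f", x$base_mean_dev_mcc), ")\n", sep = "")
  cat("  test MCC ", sprintf("%.3f", x$metrics$test$mcc),
      ", AUC ", sprintf("%.3f", x$metrics$test$auc), "\n", sep = "")
  invisible(x)
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_split(result$split, file.path(out_dir, "split.csv"))
  manifest <- lapply(result$ensemble$members, function(cl) {
    list(algorithm = cl$algorithm, hyperparameters = cl$hyperparameters,
         seed = cl$seed, subsample_ids = cl$subsample_ids,
         mcc_train = cl$mcc_train, mcc_dev = cl$mcc_dev)
  })
  jsonlite::write_json(
    list(selection = result$ensemble$strategy,
         classifier_ids = result$mlr_dev$classifier_ids,
         members = manifest,
         seed = result$config$seed),
    file.path(out_dir, "ensemble_manifest.json"), auto_unbox = TRUE)
  for (set in c("dev", "test")) {
    probs <- result[[paste0(set, "_probs")]]
    lab <- result[[paste0(set, "_labels")]]
    utils::write.csv(
      data.frame(compound_id = names(lab), probability = probs, label = lab),
      file.path(out_dir, paste0("predictions_", set, ".csv")),
      row.names = FALSE)
  }
  jsonlite::write_json(
    list(dev = unclass(result$metrics$dev), test = unclass(result$metrics$test),
         base_mean_dev_mcc = result$base_mean_dev_mcc),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$prioritization,
                   file.path(out_dir, "threshold_prioritization.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
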