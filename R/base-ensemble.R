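# Bulk training of base classifiers on random 80% subsamples of the
# training set, hyperparameter search by mean development-set MCC, and the
# two selection strategies that define the model-level representation.

# Draw a subsample containing both classes; bounded retries then error.
draw_subsample <- function(n, frac, y, max_retries = 10L) {
  size <- round(frac * n)
  for (attempt in seq_len(max_retries)) {
    idx <- sample.int(n, size, replace = FALSE)
    if (length(unique(y[idx])) == 2L) return(idx)
  }
  stop("could not draw a subsample containing both classes after ",
       max_retries, " attempts")
}

mcc_from_counts <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

mcc_score <- function(probs, labels, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  mcc_from_counts(sum(pred == 1 & labels == 1), sum(pred == 0 & labels == 0),
                  sum(pred == 1 & labels == 0), sum(pred == 0 & labels == 1))
}

#' Hyperparameter search by bootstrap aggregating
#'
#' For every combination in the grid, `n_models` classifiers are fitted on
#' independent random subsamples (80% of the training rows, drawn without
#' replacement within each subsample) and scored by Matthews correlation
#' coefficient on the development set. The combination with the highest
#' mean development-set MCC wins (first on ties).
#'
#' @param algorithm One of the five base algorithms.
#' @param grid Named list of parameter value vectors (crossed); see
#'   [default_grids()].
#' @param train_x,train_y Training feature matrix and 0/1 labels.
#' @param dev_x,dev_y Development feature matrix and labels.
#' @param n_models Classifiers fitted per combination (default 100).
#' @param subsample_frac Fraction of training rows per subsample (0.8).
#' @param seed Integer seed governing all subsampling.
#' @param replace Draw subsamples with replacement (classical bootstrap)
#'   instead of the default without-replacement subsampling.
#' @return A list with `best` (named list, the winning combination) and
#'   `scores` (data frame of combinations with their mean dev MCC).
#' @export
bootstrap_hyperparameter_search <- function(algorithm, grid, train_x, train_y,
                                            dev_x, dev_y, n_models = 100L,
                                            subsample_frac = 0.8, seed = 1L,
                                            replace = FALSE) {
  combos <- expand_grid_combos(grid)
  mean_mcc <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    combo <- as.list(combos[ci, , drop = FALSE])
    pop <- train_base_population(algorithm, combo, train_x, train_y,
                                 dev_x, dev_y, n_models = n_models,
                                 subsample_frac = subsample_frac,
                                 seed = seed, replace = replace)
    mean_mcc[ci] <- mean(vapply(pop, `[[`, numeric(1), "mcc_dev"))
  }
  scores <- cbind(combos, mean_dev_mcc = mean_mcc)
  list(best = as.list(combos[which.max(mean_mcc), , drop = FALSE]),
       scores = scores)
}

#' Train a population of base classifiers
#'
#' Fits `n_models` classifiers of one algorithm at a fixed hyperparameter
#' combination, each on its own random subsample of the training set, and
#' records each member's MCC on the full training set and on the
#' development set (the quantities the selection strategies filter on).
#'
#' @inheritParams bootstrap_hyperparameter_search
#' @param hyperparameters Named list, one value per parameter.
#' @param score_train How `mcc_train` is computed: on the full training set
#'   (default, used by the selection strategies) or on each member's
#'   out-of-bag rows.
#' @return List of `TrainedBaseClassifier` objects, each with fields
#'   `algorithm`, `hyperparameters`, `seed`, `subsample_ids`, `model`,
#'   `mcc_train`, `mcc_dev`.
#' @export
train_base_population <- function(algorithm, hyperparameters, train_x, train_y,
                                  dev_x, dev_y, n_models = 1000L,
                                  subsample_frac = 0.8, seed = 1L,
                                  replace = FALSE, score_train = c("full", "oob")) {
  score_train <- match.arg(score_train)
  algorithm <- match.arg(algorithm, BASE_ALGORITHMS)
  n <- nrow(train_x)
  lapply(seq_len(n_models), function(i) {
    member_seed <- seed + i - 1L
    set.seed(member_seed)
    idx <- if (replace) {
      # classical bootstrap; redraw until both classes present
      repeat {
        cand <- sample.int(n, round(subsample_frac * n), replace = TRUE)
        if (length(unique(train_y[cand])) == 2L) break
      }
      cand
    } else {
      draw_subsample(n, subsample_frac, train_y)
    }
    model <- fit_base(algorithm, hyperparameters,
                      train_x[idx, , drop = FALSE], train_y[idx])
    set.seed(member_seed)  # KNN vote ties are resolved randomly; pin them
    train_rows <- if (score_train == "full") seq_len(n) else setdiff(seq_len(n), idx)
    mcc_tr <- mcc_score(predict_base(model, train_x[train_rows, , drop = FALSE]),
                        train_y[train_rows])
    set.seed(member_seed)
    mcc_de <- mcc_score(predict_base(model, dev_x), dev_y)
    structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                   seed = member_seed, subsample_ids = idx, model = model,
                   mcc_train = mcc_tr, mcc_dev = mcc_de),
              class = "TrainedBaseClassifier")
  })
}

split_by_algorithm <- function(classifiers) {
  split(classifiers, vapply(classifiers, `[[`, character(1), "algorithm"))
}

new_selected_ensemble <- function(strategy, members) {
  if (!length(members)) stop("selection produced an empty ensemble")
  counts <- table(vapply(members, `[[`, character(1), "algorithm"))
  structure(list(strategy = strategy, members = members,
                 counts = as.list(counts)),
            class = "SelectedEnsemble")
}

#' @export
print.SelectedEnsemble <- function(x, ...) {
  cat("<SelectedEnsemble> strategy ", x$strategy, ", ", length(x$members),
      " members (", paste(names(x$counts), unlist(x$counts),
                          sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Original selection: central 5-95 percentile band of dev-set MCC
#'
#' Within each algorithm's population the members are rank-ordered by
#' development-set MCC; the lowest `ceiling(0.05 n)` and highest
#' `ceiling(0.05 n)` order statistics mark the band edges and members whose
#' MCC lies inclusively between the adjacent inner values are kept (so 100
#' members with distinct MCCs keep 90, and an all-equal population keeps
#' everyone). Survivors from all algorithms are concatenated.
#'
#' @param classifiers List of `TrainedBaseClassifier` (any mix of
#'   algorithms; typically 100 per algorithm).
#' @return A `SelectedEnsemble` with `strategy = "original"`.
#' @export
select_original <- function(classifiers) {
  groups <- split_by_algorithm(classifiers)
  members <- list()
  for (grp in groups) {
    mcc <- vapply(grp, `[[`, numeric(1), "mcc_dev")
    n <- length(mcc)
    trim <- ceiling(0.05 * n)
    srt <- sort(mcc)
    lo <- srt[min(trim + 1L, n)]
    hi <- srt[max(n - trim, 1L)]
    if (lo > hi) { lo <- srt[trim]; hi <- srt[trim] }  # tiny-n guard
    members <- c(members, grp[mcc >= lo & mcc <= hi])
  }
  new_selected_ensemble("original", members)
}

#' Supervised selection: above-average MCC on both training and development
#'
#' Within each algorithm's population, keeps exactly the members whose MCC
#' on the training set strictly exceeds the population's mean training MCC
#' AND whose development-set MCC strictly exceeds the mean development MCC.
#' Survivors from all algorithms are concatenated. Errors only if every
#' algorithm's selection is empty.
#'
#' @param classifiers List of `TrainedBaseClassifier` (typically 1000 per
#'   algorithm).
#' @return A `SelectedEnsemble` with `strategy = "supervised"`.
#' @export
select_supervised <- function(classifiers) {
  groups <- split_by_algorithm(classifiers)
  members <- list()
  for (grp in groups) {
    mt <- vapply(grp, `[[`, numeric(1), "mcc_train")
    md <- vapply(grp, `[[`, numeric(1), "mcc_dev")
    keep <- mt > mean(mt) & md > mean(md)
    members <- c(members, grp[keep])
  }
  new_selected_ensemble("supervised", members)
}

#' Model-level representation: base-classifier probabilities per compound
#'
#' Runs every member of a selected ensemble over a descriptor matrix and
#' assembles the compounds-by-members matrix of predicted carcinogen
#' probabilities. This matrix is the meta-classifier's input: each compound
#' is represented by the vector of opinions of the selected classifiers.
#'
#' @param ensemble A [select_original()] / [select_supervised()] result.
#' @param m A [descriptor_matrix()] (or plain matrix) in the training
#'   feature space.
#' @return A list of class `ModelLevelRepresentation`: `compound_ids`,
#'   `classifier_ids`, `probs` (matrix, entries in \[0, 1\]).
#' @export
predict_probabilities <- function(ensemble, m) {
  stopifnot(inherits(ensemble, "SelectedEnsemble"))
  vals <- if (inherits(m, "DescriptorMatrix")) m$values else as.matrix(m)
  ids <- rownames(vals) %||% paste0("cmpd", seq_len(nrow(vals)))
  cls_ids <- vapply(ensemble$members, function(cl) {
    paste0(cl$algorithm, "_s", cl$seed)
  }, character(1))
  probs <- vapply(ensemble$members, function(cl) {
    set.seed(cl$seed)
    predict_base(cl$model, vals)
  }, numeric(nrow(vals)))
  probs <- matrix(probs, nrow = nrow(vals),
                  dimnames = list(ids, make.unique(cls_ids)))
  structure(list(compound_ids = ids, classifier_ids = colnames(probs),
                 probs = probs),
            class = "ModelLevelRepresentation")
}

#' @export
print.ModelLevelRepresentation <- function(x, ...) {
  cat("<ModelLevelRepresentation> ", nrow(x$probs), " compounds x ",
      ncol(x$probs), " classifiers\n", sep = "")
  invisible(x)
}
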