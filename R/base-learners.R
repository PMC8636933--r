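# Thin uniform wrappers around the five base-learning algorithms. Each
# returns a fitted handle with enough state to produce P(positive class)
# for new compounds. Labels are 0/1 integers with 1 = carcinogen.

BASE_ALGORITHMS <- c("KNN", "LR", "SVM", "RF", "XGBoost")

#' Default hyperparameter grids for the five base algorithms
#'
#' Small, conventional grids intended as a starting point; the grids used
#' in any given run are fully configurable and can be replaced wholesale
#' (e.g. by a published supplementary grid). Each grid is a named list of
#' parameter value vectors that are crossed.
#'
#' @return Named list of grids keyed by algorithm.
#' @export
default_grids <- function() {
  list(
    KNN = list(k = c(3L, 5L, 7L, 9L)),
    LR = list(lambda = c(1e-4, 1e-2), alpha = 0),
    SVM = list(cost = c(0.1, 1, 10), gamma_scale = 1),
    RF = list(ntree = 100L, mtry_frac = c(0.33, 0.6)),
    XGBoost = list(nrounds = 50L, max_depth = c(3L, 6L), eta = 0.3)
  )
}

#' Expand a hyperparameter grid into combinations
#'
#' @param grid Named list of parameter value vectors.
#' @return A data frame with one row per combination.
#' @export
expand_grid_combos <- function(grid) {
  if (!length(grid)) stop("empty hyperparameter grid")
  expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Fit one base classifier
#'
#' @param algorithm One of `"KNN"`, `"LR"`, `"SVM"`, `"RF"`, `"XGBoost"`.
#' @param hyperparameters Named list of parameter values for that
#'   algorithm (see [default_grids()] for the recognised names).
#' @param x Numeric feature matrix (training rows).
#' @param y Binary 0/1 labels aligned with `x`.
#' @return A fitted handle of class `BaseLearner` usable with
#'   [predict_base()].
#' @export
fit_base <- function(algorithm, hyperparameters, x, y) {
  algorithm <- match.arg(algorithm, BASE_ALGORITHMS)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  hp <- hyperparameters
  fit <- switch(algorithm,
    KNN = list(x = x, y = y, k = as.integer(hp$k %||% 5L)),
    LR = glmnet::glmnet(x, y, family = "binomial",
                        alpha = hp$alpha %||% 0,
                        lambda = hp$lambda %||% 1e-4),
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)),
                     kernel = "radial",
                     cost = hp$cost %||% 1,
                     gamma = (hp$gamma_scale %||% 1) / ncol(x),
                     probability = TRUE),
    RF = randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = as.integer(hp$ntree %||% 100L),
      mtry = max(1L, floor((hp$mtry_frac %||% 0.33) * ncol(x)))),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = as.integer(hp$max_depth %||% 6L),
                    eta = hp$eta %||% 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = as.integer(hp$nrounds %||% 50L), verbose = 0)
  )
  structure(list(algorithm = algorithm, hyperparameters = hp, fit = fit,
                 feature_names = colnames(x)),
            class = "BaseLearner")
}

#' Predicted probability of the positive class
#'
#' @param model A [fit_base()] handle.
#' @param x Feature matrix with the same columns (names and order) as at
#'   training time.
#' @return Numeric vector of P(carcinogen) in \[0, 1\].
#' @export
predict_base <- function(model, x) {
  stopifnot(inherits(model, "BaseLearner"))
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(x)) || !identical(colnames(x), model$feature_names)) {
      miss <- setdiff(model$feature_names, colnames(x) %||% character(0))
      stop("feature space mismatch",
           if (length(miss)) paste0("; missing features: ",
                                    paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  p <- switch(model$algorithm,
    KNN = {
      pred <- class::knn(model$fit$x, x,
                         factor(model$fit$y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    LR = as.numeric(stats::predict(model$fit, x, type = "response")),
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RF = stats::predict(model$fit, x, type = "prob")[, "1"],
    XGBoost = as.numeric(stats::predict(model$fit,
                                        xgboost::xgb.DMatrix(x, nthread = 1L)))
  )
  unname(pmin(1, pmax(0, p)))
}
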