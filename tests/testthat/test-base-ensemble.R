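test_that("every base algorithm fits and emits probabilities in [0, 1]", {
  d <- separable_data(n = 60)
  holdout <- separable_data(n = 30, seed = 43)
  grids <- default_grids()
  for (alg in c("KNN", "LR", "SVM", "RF", "XGBoost")) {
    combo <- lapply(grids[[alg]], `[`, 1)
    set.seed(1)
    model <- fit_base(alg, combo, d$x, d$y)
    p <- predict_base(model, holdout$x)
    expect_length(p, 30L)
    expect_true(all(p >= 0 & p <= 1), info = alg)
    # separable by construction: every algorithm should do well
    expect_gt(roc_auc(p, holdout$y), 0.85)
  }
})

test_that("feature-space mismatch is reported with the missing features", {
  d <- separable_data()
  model <- fit_base("LR", list(lambda = 1e-3, alpha = 0), d$x, d$y)
  bad <- d$x[, 1:2]
  expect_error(predict_base(model, bad), "f3")
})

test_that("hyperparameter search returns the single combination trivially", {
  d <- separable_data(n = 40)
  dev <- separable_data(n = 20, seed = 7)
  res <- bootstrap_hyperparameter_search("KNN", list(k = 5L), d$x, d$y,
                                         dev$x, dev$y, n_models = 3L, seed = 1L)
  expect_equal(res$best$k, 5L)
  expect_equal(nrow(res$scores), 1L)
})

test_that("the search prefers the plainly better hyperparameter arm", {
  # k = 1 separates the two tight clusters; k = 45 averages over nearly the
  # whole 48-row subsample and cannot
  d <- separable_data(n = 60, shift = 4)
  dev <- separable_data(n = 30, shift = 4, seed = 7)
  res <- bootstrap_hyperparameter_search("KNN", list(k = c(1L, 45L)),
                                         d$x, d$y, dev$x, dev$y,
                                         n_models = 10L, seed = 1L)
  expect_equal(res$best$k, 1L)
  scores <- res$scores
  expect_gt(scores$mean_dev_mcc[scores$k == 1],
            scores$mean_dev_mcc[scores$k == 45])
})

test_that("the search score table is reproducible under a fixed seed", {
  d <- separable_data(n = 40)
  dev <- separable_data(n = 20, seed = 7)
  r1 <- bootstrap_hyperparameter_search("RF", list(ntree = 30L, mtry_frac = c(0.33, 0.6)),
                                        d$x, d$y, dev$x, dev$y,
                                        n_models = 4L, seed = 5L)
  r2 <- bootstrap_hyperparameter_search("RF", list(ntree = 30L, mtry_frac = c(0.33, 0.6)),
                                        d$x, d$y, dev$x, dev$y,
                                        n_models = 4L, seed = 5L)
  expect_identical(r1$scores, r2$scores)
})

test_that("population training records subsamples, seeds and both MCCs", {
  d <- separable_data(n = 50)
  dev <- separable_data(n = 20, seed = 7)
  pop <- train_base_population("LR", list(lambda = 1e-3, alpha = 0),
                               d$x, d$y, dev$x, dev$y,
                               n_models = 6L, seed = 9L)
  expect_length(pop, 6L)
  for (cl in pop) {
    expect_s3_class(cl, "TrainedBaseClassifier")
    expect_length(cl$subsample_ids, round(0.8 * 50))
    expect_true(cl$mcc_train >= -1 && cl$mcc_train <= 1)
    expect_true(cl$mcc_dev >= -1 && cl$mcc_dev <= 1)
  }
  expect_equal(vapply(pop, `[[`, integer(1), "seed"), 9L + 0:5)
  # fixed seed: bit-identical dev MCCs on rerun
  pop2 <- train_base_population("LR", list(lambda = 1e-3, alpha = 0),
                                d$x, d$y, dev$x, dev$y,
                                n_models = 6L, seed = 9L)
  expect_identical(vapply(pop, `[[`, numeric(1), "mcc_dev"),
                   vapply(pop2, `[[`, numeric(1), "mcc_dev"))
})

test_that("original selection keeps the central percentile band", {
  # 100 distinct values -> 90 kept
  pop <- stub_population("KNN", runif(100), seq(0.001, 1, length.out = 100))
  sel <- select_original(pop)
  expect_length(sel$members, 90L)
  kept <- vapply(sel$members, `[[`, numeric(1), "mcc_dev")
  srt <- sort(seq(0.001, 1, length.out = 100))
  expect_setequal(kept, srt[6:95])  # brute-force rank filter
  # 10 distinct values -> 8 kept
  pop10 <- stub_population("LR", runif(10), (1:10) / 10)
  expect_length(select_original(pop10)$members, 8L)
  # all equal -> everyone kept
  flat <- stub_population("RF", rep(0.5, 30), rep(0.4, 30))
  expect_length(select_original(flat)$members, 30L)
})

test_that("supervised selection applies the dual above-mean predicate", {
  pop <- stub_population("SVM", c(0.1, 0.3, 0.5, 0.7), c(0.2, 0.4, 0.6, 0.8))
  sel <- select_supervised(pop)
  expect_length(sel$members, 2L)
  expect_setequal(vapply(sel$members, `[[`, numeric(1), "mcc_dev"), c(0.6, 0.8))
  # all members identical: strict inequality keeps nobody -> error
  flat <- stub_population("SVM", rep(0.5, 5), rep(0.5, 5))
  expect_error(select_supervised(flat), "empty")
  # a strictly dominating member is always selected
  dom <- stub_population("KNN", c(0.2, 0.3, 0.9), c(0.1, 0.2, 0.95))
  expect_true(0.95 %in% vapply(select_supervised(dom)$members, `[[`,
                               numeric(1), "mcc_dev"))
})

test_that("supervised selection matches a brute-force filter on random populations", {
  set.seed(123)
  for (trial in 1:50) {
    n <- sample(10:1000, 1)
    algs <- sample(c("KNN", "LR", "RF"), 1)
    mt <- runif(n, -1, 1); md <- runif(n, -1, 1)
    pop <- stub_population(algs, mt, md)
    keep <- mt > mean(mt) & md > mean(md)
    if (!any(keep)) {
      expect_error(select_supervised(pop), "empty")
      next
    }
    sel <- select_supervised(pop)
    expect_equal(length(sel$members), sum(keep))
    expect_equal(vapply(sel$members, `[[`, numeric(1), "mcc_train"), mt[keep])
    # selection keeps above-average members
    expect_gte(mean(md[keep]), mean(md))
    expect_lt(length(sel$members), n)
  }
})

test_that("selection strategies operate per algorithm before concatenating", {
  pop <- c(stub_population("KNN", c(0.1, 0.9), c(0.1, 0.9)),
           stub_population("RF", c(0.5, 0.6), c(0.2, 0.8)))
  sel <- select_supervised(pop)
  expect_equal(sort(names(sel$counts)), c("KNN", "RF"))
  expect_equal(sel$counts$KNN, 1L)
  expect_equal(sel$counts$RF, 1L)
})

test_that("model-level representation matches member-by-member prediction", {
  d <- separable_data(n = 50)
  dev <- separable_data(n = 15, seed = 3)
  pop <- train_base_population("RF", list(ntree = 30L, mtry_frac = 0.33),
                               d$x, d$y, dev$x, dev$y, n_models = 4L, seed = 21L)
  ens <- structure(list(strategy = "supervised", members = pop,
                        counts = list(RF = 4L)), class = "SelectedEnsemble")
  mlr <- predict_probabilities(ens, dev$x)
  expect_equal(dim(mlr$probs), c(15L, 4L))
  expect_true(all(mlr$probs >= 0 & mlr$probs <= 1))
  for (j in 1:4) {
    set.seed(pop[[j]]$seed)
    expect_equal(unname(mlr$probs[, j]), predict_base(pop[[j]]$model, dev$x))
  }
})
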