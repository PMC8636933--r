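# Shared fixtures and independent oracles used across the suite.

make_dm <- function(values, kind = "continuous", ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("c", seq_len(nrow(values)))
  descriptor_matrix(values, ids, kind)
}

# Minimal stand-in for a trained base classifier carrying only the fields
# the selection strategies read.
stub_classifier <- function(algorithm, mcc_train, mcc_dev) {
  structure(list(algorithm = algorithm, hyperparameters = list(),
                 seed = NA_integer_, subsample_ids = integer(0),
                 model = NULL, mcc_train = mcc_train, mcc_dev = mcc_dev),
            class = "TrainedBaseClassifier")
}

stub_population <- function(algorithm, mcc_train, mcc_dev) {
  Map(function(a, b) stub_classifier(algorithm, a, b), mcc_train, mcc_dev)
}

# Independent Kennard-Stone oracle: literal max-min search written from
# the definition with explicit loops, no shared code with the implementation.
brute_force_ks <- function(points, n_select) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  }
  best_i <- 1L; best_j <- 2L; best_d <- -Inf
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (d[i, j] > best_d) { best_d <- d[i, j]; best_i <- i; best_j <- j }
  }
  sel <- c(best_i, best_j)
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    scores <- vapply(cand, function(c) min(d[c, sel]), numeric(1))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# Separable two-class training data for base-learner tests.
separable_data <- function(n = 60L, p = 4L, shift = 3, seed = 42L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p) + shift * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# Small fast pipeline configuration reused by pipeline tests.
fast_config <- function(seed, ...) {
  run_config(
    split_sizes = c(70, 25, 25),
    algorithms = c("LR", "KNN"),
    grids = list(LR = list(lambda = 1e-3, alpha = 0), KNN = list(k = 5L)),
    n_search_models = 0L, n_population_models = 8L,
    meta = list(epochs = 60L), seed = seed, ...)
}
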