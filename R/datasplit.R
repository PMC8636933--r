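#' Kennard-Stone representative sampling
#'
#' Deterministic max-min selection in Euclidean descriptor space: the first
#' two selections are a maximally distant pair (the lower original index
#' emitted first); each subsequent selection maximizes its minimum distance
#' to the already-selected set. Ties at any step are broken by lowest
#' original index, so the ordering is fully reproducible with no random
#' seed.
#'
#' @param m A [descriptor_matrix()] (or a plain numeric matrix).
#' @param n_select Number of compounds to select, between 2 and the number
#'   of rows.
#' @return Character vector of selected compound ids in selection order
#'   (integer indices when `m` is a bare matrix without rownames).
#' @export
kennard_stone <- function(m, n_select) {
  vals <- if (inherits(m, "DescriptorMatrix")) m$values else as.matrix(m)
  n <- nrow(vals)
  if (n_select < 2L) stop("n_select must be at least 2")
  if (n_select > n) stop("n_select (", n_select, ") exceeds compound count (", n, ")")
  d <- as.matrix(stats::dist(vals))
  # seed pair: maximal distance, lexicographically smallest index pair on ties
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which.max(d[i, (i + 1L):n]) + i
    if (d[i, j] > best_d) { best_d <- d[i, j]; best <- c(i, j) }
  }
  selected <- best
  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(d[, selected[1L]], d[, selected[2L]])
  while (length(selected) < n_select) {
    nxt <- remaining[which.max(min_d[remaining])]   # which.max takes first on ties
    selected <- c(selected, nxt)
    remaining <- remaining[remaining != nxt]
    min_d <- pmin(min_d, d[, nxt])
  }
  selected <- as.integer(unname(selected))
  ids <- rownames(vals)
  if (is.null(ids)) selected else ids[selected]
}

#' Three-way representative split
#'
#' Partitions the compounds into training, development and test sets by
#' sequential Kennard-Stone sampling: the training set is selected from all
#' compounds, the development set is selected by re-running Kennard-Stone
#' on the remainder, and the residue forms the test set. The split is
#' deterministic (no randomness).
#'
#' @param m A [descriptor_matrix()].
#' @param sizes Integer vector `c(n_train, n_dev, n_test)` summing to the
#'   number of compounds.
#' @return A list of class `SplitAssignment` with `train_ids`, `dev_ids`,
#'   `test_ids`, `method` and `distance_kind`.
#' @export
#' @examples
#' m <- descriptor_matrix(matrix(rnorm(40), 10, 4), paste0("c", 1:10), "continuous")
#' s <- three_way_split(m, c(6, 2, 2))
#' lengths(s[c("train_ids", "dev_ids", "test_ids")])
three_way_split <- function(m, sizes) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  if (length(sizes) != 3L) stop("sizes must be c(n_train, n_dev, n_test)")
  n <- nrow(m$values)
  if (sum(sizes) != n) {
    stop("sizes sum to ", sum(sizes), " but the matrix has ", n, " compounds")
  }
  train_ids <- kennard_stone(m, sizes[1L])
  rest <- setdiff(m$compound_ids, train_ids)
  dev_ids <- if (sizes[2L] >= 2L) {
    kennard_stone(subset_compounds(m, rest), sizes[2L])
  } else {
    rest[seq_len(sizes[2L])]
  }
  test_ids <- setdiff(rest, dev_ids)
  structure(
    list(train_ids = train_ids, dev_ids = dev_ids, test_ids = test_ids,
         method = "kennard_stone_sequential", distance_kind = "euclidean"),
    class = "SplitAssignment")
}

#' @export
print.SplitAssignment <- function(x, ...) {
  cat("<SplitAssignment> train ", length(x$train_ids), " / dev ",
      length(x$dev_ids), " / test ", length(x$test_ids),
      " (", x$method, ", ", x$distance_kind, ")\n", sep = "")
  invisible(x)
}

#' Write a split assignment as a two-column CSV
#'
#' @param split A [three_way_split()] result.
#' @param path Output CSV path with columns `compound_id`, `subset`.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    compound_id = c(split$train_ids, split$dev_ids, split$test_ids),
    subset = rep(c("train", "dev", "test"),
                 c(length(split$train_ids), length(split$dev_ids),
                   length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
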