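#' Drop zero-variance descriptors
#'
#' Removes every column whose values are all identical; such descriptors
#' carry no information for classification. Column order is preserved and
#' the dropped feature names are recorded in the result's metadata.
#'
#' @param m A [descriptor_matrix()].
#' @return A `DescriptorMatrix` without constant columns; its metadata
#'   element `dropped_zero_variance` lists the removed features.
#' @export
remove_zero_variance <- function(m) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  constant <- apply(m$values, 2L, function(col) all(col == col[1L]))
  if (all(constant)) stop("all descriptors are constant; nothing left to model")
  keep <- which(!constant)
  meta <- m$metadata
  meta$dropped_zero_variance <- m$feature_names[constant]
  descriptor_matrix(m$values[, keep, drop = FALSE], m$compound_ids, m$kind,
                    m$feature_names[keep], meta)
}

#' Drop highly correlated descriptors
#'
#' Scans columns left to right; a column is dropped when its correlation
#' with any earlier retained column exceeds `threshold` in magnitude
#' (strictly greater). The keep-first scan is deterministic and
#' order-stable, so the first member of each correlated group survives.
#' Zero-variance columns must have been removed beforehand (correlation is
#' undefined for constants).
#'
#' @param m A [descriptor_matrix()] with no constant columns.
#' @param threshold Correlation cut-off; pairs above it are considered
#'   redundant. Default 0.9.
#' @param use_absolute Compare `|r|` (default) rather than signed `r`;
#'   anti-correlated descriptors are equally redundant.
#' @return A `DescriptorMatrix`; metadata element `dropped_correlated` is a
#'   data frame naming each dropped feature and the retained feature it
#'   correlated with.
#' @export
correlation_filter <- function(m, threshold = 0.9, use_absolute = TRUE) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  if (any(apply(m$values, 2L, function(col) all(col == col[1L])))) {
    stop("correlation_filter requires zero-variance columns to be removed first")
  }
  p <- ncol(m$values)
  cc <- suppressWarnings(stats::cor(m$values))
  if (use_absolute) cc <- abs(cc)
  kept <- integer(0)
  dropped <- integer(0)
  partner <- integer(0)
  for (j in seq_len(p)) {
    over <- kept[cc[j, kept] > threshold]
    if (length(over)) {
      dropped <- c(dropped, j)
      partner <- c(partner, over[1L])
    } else {
      kept <- c(kept, j)
    }
  }
  meta <- m$metadata
  meta$dropped_correlated <- data.frame(
    feature = m$feature_names[dropped],
    correlated_with = m$feature_names[partner],
    stringsAsFactors = FALSE)
  descriptor_matrix(m$values[, kept, drop = FALSE], m$compound_ids, m$kind,
                    m$feature_names[kept], meta)
}

#' Two-step descriptor preprocessing
#'
#' The standard cleanup applied to every representation before modelling:
#' remove zero-variance descriptors, then keep one descriptor per group
#' with pairwise correlation above 0.9. Idempotent.
#'
#' @inheritParams correlation_filter
#' @return A preprocessed `DescriptorMatrix` with both drop logs in its
#'   metadata.
#' @export
preprocess_descriptors <- function(m, threshold = 0.9, use_absolute = TRUE) {
  correlation_filter(remove_zero_variance(m), threshold, use_absolute)
}

#' Write a JSON log of dropped descriptors
#'
#' @param m A preprocessed [descriptor_matrix()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(m, path) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  log <- list(
    zero_variance = as.list(m$metadata$dropped_zero_variance %||% character(0)),
    correlated = m$metadata$dropped_correlated %||%
      data.frame(feature = character(0), correlated_with = character(0))
  )
  jsonlite::write_json(log, path, auto_unbox = FALSE, dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
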