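#' Tanimoto coefficient for continuous descriptor vectors
#'
#' The continuous generalization of the Tanimoto similarity,
#' \deqn{S_{A,B} = \frac{\sum_j x_j y_j}{\sum_j x_j^2 + \sum_j y_j^2 - \sum_j x_j y_j},}
#' bounded in \[-1/3, 1\]. When both vectors are all-zero the ratio is 0/0;
#' the coefficient is then defined as 0 ("no evidence of similarity") with a
#' warning.
#'
#' @param x,y Equal-length numeric vectors.
#' @return A single similarity coefficient.
#' @export
tanimoto_continuous <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vector length mismatch: ", length(x), " vs ", length(y))
  }
  num <- sum(x * y)
  den <- sum(x^2) + sum(y^2) - num
  if (den == 0) {
    warning("both vectors all-zero; Tanimoto defined as 0")
    return(0)
  }
  num / den
}

#' Tanimoto coefficient for bit vectors
#'
#' The classic fingerprint similarity \eqn{c / (a + b - c)} where `a` and
#' `b` count the set bits of each vector and `c` the bits set in both. The
#' all-zero/all-zero pair is defined as 0 with a warning.
#'
#' @param x,y Equal-length vectors with entries in \{0, 1\}.
#' @return A similarity coefficient in \[0, 1\].
#' @export
tanimoto_binary <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vector length mismatch: ", length(x), " vs ", length(y))
  }
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("tanimoto_binary requires 0/1 entries")
  }
  a <- sum(x); b <- sum(y); cc <- sum(x * y)
  den <- a + b - cc
  if (den == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  cc / den
}

#' Within-class pairwise similarity summary
#'
#' Scores every unordered pair of compounds belonging to one class with the
#' Tanimoto coefficient appropriate to the representation kind (bit-vector
#' form for binary fingerprints, continuous form otherwise) and summarizes
#' the distribution. Used to compare the discrimination power of different
#' chemical representations: a representation under which same-class
#' compounds are mutually similar clusters the classes more tightly.
#'
#' @param m A [descriptor_matrix()].
#' @param labels Vector of class labels aligned with `m`'s rows.
#' @param class_label The class to summarize.
#' @param keep_values Return the full vector of pairwise coefficients.
#' @return A list of class `SimilaritySummary`: `class_label`, `n_pairs`,
#'   `mean`, `sd` and (optionally) `values`.
#' @export
within_class_similarity <- function(m, labels, class_label, keep_values = FALSE) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  if (length(labels) != nrow(m$values)) {
    stop("labels length does not match compound count")
  }
  rows <- which(labels == class_label)
  k <- length(rows)
  if (k < 2L) stop("class '", class_label, "' has ", k, " member(s); need at least 2")
  fun <- if (m$kind == "binary_fingerprint") tanimoto_binary else tanimoto_continuous
  vals <- numeric(k * (k - 1L) / 2L)
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    xi <- m$values[rows[i], ]
    for (j in seq.int(i + 1L, k)) {
      idx <- idx + 1L
      vals[idx] <- fun(xi, m$values[rows[j], ])
    }
  }
  structure(
    list(class_label = class_label, n_pairs = length(vals),
         mean = mean(vals), sd = stats::sd(vals),
         values = if (keep_values) vals else NULL),
    class = "SimilaritySummary")
}

#' @export
print.SimilaritySummary <- function(x, ...) {
  cat("<SimilaritySummary> class ", x$class_label, ": ", x$n_pairs,
      " pairs, Tanimoto ", sprintf("%.3f +/- %.3f", x$mean, x$sd), "\n", sep = "")
  invisible(x)
}
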