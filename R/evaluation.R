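# Confusion-matrix bookkeeping and the six headline metrics (MCC, F1,
# accuracy, balanced accuracy, sensitivity, specificity), plus AUC,
# PPV/NPV, chi-square threshold prioritization and the two conventional
# ensemble baselines used for comparison.

#' Confusion counts at a probability threshold
#'
#' A probability greater than or equal to the threshold is called positive
#' (carcinogen); the boundary convention matches the average-probability
#' consensus rule, under which a mean below 0.5 is a negative call and
#' everything else positive.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels Binary 0/1 labels, aligned with `probs`.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `ConfusionCounts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels)) {
    stop("probs and labels lengths differ (", length(probs), " vs ",
         length(labels), ")")
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(probs >= threshold)
  confusion_counts(sum(pred == 1 & labels == 1), sum(pred == 0 & labels == 0),
                   sum(pred == 1 & labels == 0), sum(pred == 0 & labels == 1))
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list of class `ConfusionCounts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' F1 = 2TP / (2TP + FP + FN), accuracy, sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP) and balanced accuracy (their mean). A zero MCC
#' denominator (e.g. everything predicted positive) yields MCC = 0 with a
#' warning; an undefined sensitivity or specificity is returned as `NaN`.
#'
#' @param counts A [confusion_counts()] object.
#' @return A list of class `MetricsBundle` with elements `mcc`, `f1`,
#'   `accuracy`, `balanced_accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) {
    warning("MCC denominator is zero; returning 0")
    0
  } else {
    (tp * tn - fp * fn) / den
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(
    mcc = mcc,
    f1 = 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / total,
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens,
    specificity = spec), class = "MetricsBundle")
}

#' @export
print.MetricsBundle <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%s = %.3f", names(vals), vals), collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive compound receives a higher score than a
#' randomly chosen negative one, with ties counted 1/2 (midranks).
#'
#' @param probs Predicted scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  if (length(probs) != length(labels)) stop("probs and labels lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC requires both classes present")
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Positive and negative predictive values
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN). A side with a zero denominator is
#' returned as `NA` with a warning.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector `c(ppv = , npv = )`.
#' @export
ppv_npv <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  ppv <- if (counts$tp + counts$fp == 0) {
    warning("no predicted positives; PPV undefined")
    NA_real_
  } else counts$tp / (counts$tp + counts$fp)
  npv <- if (counts$tn + counts$fn == 0) {
    warning("no predicted negatives; NPV undefined")
    NA_real_
  } else counts$tn / (counts$tn + counts$fn)
  c(ppv = ppv, npv = npv)
}

#' Threshold prioritization table
#'
#' For each probability cut-off, tabulates the 2x2 contingency table of
#' predicted call against actual class, tests the association with a
#' chi-square test and reports PPV and NPV. High-threshold rows with high
#' PPV indicate that large predicted probabilities can prioritize likely
#' carcinogens; low-threshold rows with high NPV indicate that small
#' probabilities flag likely non-carcinogens. The chi-square flavour is
#' configurable because printed p-values in the literature rarely pin down
#' the variant; Pearson without continuity correction is the default.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 labels.
#' @param thresholds Cut-offs strictly inside (0, 1); default 0.1 to 0.9 by
#'   0.1.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A data frame with one row per threshold: `threshold`, `tp`,
#'   `fp`, `fn`, `tn`, `p_value`, `ppv`, `npv`.
#' @export
threshold_prioritization <- function(probs, labels,
                                     thresholds = seq(0.1, 0.9, by = 0.1),
                                     correct = FALSE) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  rows <- lapply(thresholds, function(t) {
    cc <- confusion_at_threshold(probs, labels, t)
    tab <- matrix(c(cc$tp, cc$fn, cc$fp, cc$tn), 2L, 2L)
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value),
      error = function(e) NA_real_)
    pn <- suppressWarnings(ppv_npv(cc))
    data.frame(threshold = t, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               p_value = p, ppv = pn[["ppv"]], npv = pn[["npv"]])
  })
  do.call(rbind, rows)
}

#' Majority-vote consensus calls
#'
#' Per compound, the class with more member votes wins; an exact tie is
#' called positive (consistent with the threshold convention that the
#' decision boundary itself is a positive call).
#'
#' @param member_calls Matrix of 0/1 votes, one column per ensemble member,
#'   one row per compound (a vector is treated as a single-member column).
#' @return Integer vector of 0/1 consensus calls.
#' @export
ensemble_majority_vote <- function(member_calls) {
  m <- as.matrix(member_calls)
  if (!all(m %in% c(0, 1))) stop("votes must be 0/1")
  as.integer(rowMeans(m) >= 0.5)
}

#' Average-probability consensus calls
#'
#' The mean member probability below 0.5 yields a non-carcinogen call and
#' anything else a carcinogen call.
#'
#' @param member_probs Matrix of probabilities in \[0, 1\], one column per
#'   member (a vector is treated as a single-member column).
#' @return Integer vector of 0/1 consensus calls.
#' @export
ensemble_average_probability <- function(member_probs) {
  m <- as.matrix(member_probs)
  if (any(m < 0 | m > 1)) stop("probabilities must lie in [0, 1]")
  as.integer(rowMeans(m) >= 0.5)
}

#' Full evaluation of a probability vector
#'
#' Convenience wrapper: confusion at 0.5, the six metrics and AUC.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A `MetricsBundle` with an additional `auc` element.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5) {
  metrics <- compute_metrics(confusion_at_threshold(probs, labels, threshold))
  metrics$auc <- roc_auc(probs, labels)
  metrics
}
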