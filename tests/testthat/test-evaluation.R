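test_that("confusion counting follows the >= threshold convention", {
  cc <- confusion_at_threshold(c(0.9, 0.1), c(1, 0))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 1, fp = 0, fn = 0))
  # a probability exactly at the threshold is a positive call
  cc2 <- confusion_at_threshold(c(0.5), c(1))
  expect_equal(cc2$tp, 1)
  cc3 <- confusion_at_threshold(rep(0, 4), c(1, 1, 0, 0))
  expect_equal(cc3$tp, 0); expect_equal(cc3$fp, 0)
  expect_error(confusion_at_threshold(c(0.5, 0.5), c(1)), "lengths differ")
})

test_that("metrics reproduce the published worked example", {
  counts <- confusion_counts(tp = 101, tn = 28, fp = 32, fn = 10)
  m <- compute_metrics(counts)
  expect_equal(round(m$mcc, 3), 0.432)
  expect_equal(round(m$accuracy, 3), 0.754)
  expect_equal(round(m$f1, 3), 0.828)
  expect_equal(round(m$balanced_accuracy, 3), 0.688)
  expect_equal(round(m$sensitivity, 3), 0.910)
  expect_equal(round(m$specificity, 3), 0.467)
})

test_that("metric edge cases behave as defined", {
  perfect <- compute_metrics(confusion_counts(tp = 10, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(mcc = 1, f1 = 1, accuracy = 1,
                                  balanced_accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  # everything predicted positive: zero denominator -> MCC 0 with warning
  expect_warning(deg <- compute_metrics(confusion_counts(tp = 8, tn = 0,
                                                         fp = 4, fn = 0)),
                 "denominator")
  expect_equal(deg$mcc, 0)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(21)
  for (trial in 1:200) {
    counts <- confusion_counts(tp = rpois(1, 20) + 1, tn = rpois(1, 20) + 1,
                               fp = rpois(1, 10), fn = rpois(1, 10))
    m <- suppressWarnings(compute_metrics(counts))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    ppv <- suppressWarnings(ppv_npv(counts)[["ppv"]])
    if (!is.na(ppv) && ppv + m$sensitivity > 0) {
      expect_equal(m$f1, 2 * ppv * m$sensitivity / (ppv + m$sensitivity))
    }
    # accuracy is a prevalence-weighted mix of sensitivity and specificity
    expect_gte(m$accuracy, min(m$sensitivity, m$specificity) - 1e-12)
    expect_lte(m$accuracy, max(m$sensitivity, m$specificity) + 1e-12)
    # |MCC| is invariant under swapping the positive and negative classes
    swapped <- suppressWarnings(compute_metrics(
      confusion_counts(tp = counts$tn, tn = counts$tp,
                       fp = counts$fn, fn = counts$fp)))
    expect_equal(m$mcc, swapped$mcc)
  }
})

test_that("AUC equals the concordant-pair oracle, exhaustively on small inputs", {
  pair_oracle <- function(probs, labels) {
    pos <- probs[labels == 1]; neg <- probs[labels == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
    total / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(14)
  for (trial in 1:100) {
    n <- sample(3:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(roc_auc(probs, labels), pair_oracle(probs, labels))
  }
  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("AUC agrees with the independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(6)
  probs <- runif(60)
  labels <- rbinom(60, 1, probs)
  labels[1:2] <- 0:1
  expect_equal(roc_auc(probs, labels),
               as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE))))
})

test_that("PPV/NPV reproduce the published threshold rows", {
  # threshold 0.3 row
  expect_equal(round(ppv_npv(confusion_counts(tp = 110, tn = 16,
                                              fp = 44, fn = 1)), 3),
               c(ppv = 0.714, npv = 0.941))
  # threshold 0.9 row
  expect_equal(round(ppv_npv(confusion_counts(tp = 47, tn = 54,
                                              fp = 6, fn = 64)), 3),
               c(ppv = 0.887, npv = 0.458))
  expect_warning(res <- ppv_npv(confusion_counts(tp = 0, tn = 3, fp = 0, fn = 1)),
                 "PPV undefined")
  expect_true(is.na(res[["ppv"]]))
})

test_that("threshold prioritization tabulates, tests and reports per cut-off", {
  # Pearson chi-square oracle on the contingency table [[110,44],[1,16]]:
  # sum over cells of (O-E)^2/E with E from the margins
  tab <- matrix(c(110, 1, 44, 16), 2, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  expect_equal(round(x2, 3), 28.879)
  p_oracle <- pchisq(x2, df = 1, lower.tail = FALSE)

  # a probability vector engineered to reproduce that table at t = 0.3
  probs <- c(rep(0.4, 110), rep(0.2, 1), rep(0.4, 44), rep(0.2, 16))
  labels <- c(rep(1, 111), rep(0, 60))
  rows <- threshold_prioritization(probs, labels, thresholds = 0.3)
  expect_equal(rows$tp, 110); expect_equal(rows$tn, 16)
  expect_equal(rows$p_value, p_oracle)
  expect_equal(round(rows$ppv, 3), 0.714)
  expect_equal(round(rows$npv, 3), 0.941)

  # perfect probabilities: every threshold row is error-free
  perfect <- threshold_prioritization(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(nrow(perfect), 9L)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))
  expect_true(all(perfect$ppv == 1) && all(perfect$npv == 1))
  expect_error(threshold_prioritization(c(0.5), c(1, 0), thresholds = 1.2),
               "strictly inside")
})

test_that("threshold table is internally consistent on random runs", {
  set.seed(33)
  probs <- runif(150)
  labels <- rbinom(150, 1, probs)
  labels[1:2] <- 0:1
  rows <- threshold_prioritization(probs, labels)
  expect_equal(nrow(rows), 9L)
  # actual positives constant across thresholds; tp non-increasing
  expect_true(all(rows$tp + rows$fn == sum(labels == 1)))
  expect_true(all(diff(rows$tp) <= 0))
})

test_that("consensus baselines follow their tie and boundary rules", {
  expect_equal(ensemble_majority_vote(matrix(c(1, 1, 0), 1)), 1L)
  expect_equal(ensemble_majority_vote(matrix(c(1, 0), 1)), 1L)   # tie -> positive
  expect_equal(ensemble_majority_vote(matrix(c(0, 1), 2)), c(0L, 1L))
  expect_equal(ensemble_average_probability(matrix(c(0.4, 0.8), 1)), 1L)
  expect_equal(ensemble_average_probability(matrix(c(0.5), 1)), 1L)  # boundary
  expect_equal(ensemble_average_probability(matrix(c(0.2), 1)), 0L)
})
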