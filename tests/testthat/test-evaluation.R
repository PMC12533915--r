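test_that("confusion metrics match hand arithmetic", {
  # the printed Cornell test-set row reconstructs to these counts
  r <- confusion_metrics(confusion_counts(
    calls = rep(c(1, 1, 0, 0), c(20, 4, 73, 107)),
    truth = rep(c(1, 0, 1, 0), c(20, 4, 73, 107))))
  expect_equal(100 * r$accuracy, 62.25, tolerance = 1e-4)
  expect_equal(100 * r$ppv, 83.33, tolerance = 1e-2)
  expect_equal(100 * r$npv, 59.44, tolerance = 1e-2)
  expect_equal(r$f1, 0.3419, tolerance = 1e-4)
  expect_equal(100 * r$sensitivity, 21.5, tolerance = 0.05)
  expect_equal(100 * r$specificity, 96.4, tolerance = 0.05)
  # accuracy CI brackets the point estimate
  expect_lte(r$accuracy_ci[["lower"]], r$accuracy)
  expect_gte(r$accuracy_ci[["upper"]], r$accuracy)
})

test_that("degenerate and symmetric confusion cases behave", {
  r <- confusion_metrics(structure(c(TP = 0, FP = 0, FN = 0, TN = 10),
                                   class = "confusion_counts"))
  expect_equal(r$accuracy, 1)
  expect_true(is.na(r$sensitivity))
  expect_true(is.na(r$ppv))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  # swapping TP<->TN and FP<->FN swaps Se<->Sp and PPV<->NPV
  a <- confusion_metrics(13, 4, 7, 21)
  b <- confusion_metrics(21, 7, 4, 13)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$ppv, b$npv)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("confusion counting equals a brute-force tally", {
  # exhaustive for n = 4, randomized for larger n
  for (n in c(4L, 50L)) {
    sets <- if (n == 4L)
      expand.grid(rep(list(0:1), 8))
    else {
      set.seed(61)
      as.data.frame(matrix(rbinom(2 * n * 5, 1, 0.5), nrow = 5 * 2))
    }
    reps <- if (n == 4L) seq_len(nrow(sets)) else 1:5
    for (i in reps) {
      if (n == 4L) {
        calls <- as.numeric(sets[i, 1:4]); truth <- as.numeric(sets[i, 5:8])
      } else {
        calls <- rbinom(n, 1, 0.4); truth <- rbinom(n, 1, 0.5)
      }
      cm <- confusion_counts(calls, truth)
      brute <- c(sum(calls & truth), sum(calls & !truth),
                 sum(!calls & truth), sum(!calls & !truth))
      expect_identical(as.integer(cm), as.integer(brute))
    }
  }
})

test_that("DeLong reproduces trivial cases and the pROC reference", {
  set.seed(101)
  labels <- rep(c(1, 0), c(25, 35))
  s_perfect <- labels + rnorm(60, 0, 1e-9)
  s_b <- rnorm(60) + labels
  expect_equal(delong_test(labels, s_b, labels)$auc_a, 1.0)
  same <- delong_test(s_b, s_b, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1.0)
  # independent reference implementation on a 60-patient fixture
  s_a <- rnorm(60) + 1.2 * labels
  ours <- delong_test(s_a, s_b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, s_a, quiet = TRUE),
                        pROC::roc(labels, s_b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$auc_a, as.numeric(pROC::auc(pROC::roc(labels, s_a,
                                                          quiet = TRUE))),
               tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-10)
  expect_error(delong_test(s_a, s_b, rep(1, 60)), "both classes")
})

test_that("tie-free AUC equals the trapezoidal ROC area", {
  set.seed(17)
  labels <- rbinom(80, 1, 0.45)
  scores <- rnorm(80) + labels  # continuous, ties a.s. absent
  # trapezoidal ROC area oracle
  th <- sort(unique(scores), decreasing = TRUE)
  roc <- t(vapply(c(Inf, th, -Inf), function(t) {
    c(fpr = mean(scores[labels == 0] >= t),
      tpr = mean(scores[labels == 1] >= t))
  }, numeric(2)))
  trap <- sum(diff(roc[, "fpr"]) *
                (roc[-1, "tpr"] + roc[-nrow(roc), "tpr"]) / 2)
  expect_equal(auc_mw(scores, labels), trap, tolerance = 1e-12)
})

test_that("McNemar uses the exact binomial tail and truncates at 1", {
  # b = 15, c = 3 discordant: two-sided exact binomial tail sum
  truth <- rep(1, 40)
  calls_a <- c(rep(1, 15), rep(0, 3), rep(1, 22))
  calls_b <- c(rep(0, 15), rep(1, 3), rep(1, 22))
  r <- mcnemar_bonferroni(calls_a, calls_b, truth)
  oracle <- 2 * sum(choose(18, 15:18)) / 2^18
  expect_equal(r$p, oracle, tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0075)
  expect_equal(r$b, 15)
  expect_equal(r$c, 3)
  # identical calls: p = 1
  expect_equal(mcnemar_bonferroni(calls_a, calls_a, truth)$p, 1.0)
  # Bonferroni is monotone and truncated
  expect_equal(mcnemar_bonferroni(calls_a, calls_b, truth,
                                  m_comparisons = 1000)$p_adjusted, 1.0)
  expect_lte(r$p_adjusted, mcnemar_bonferroni(calls_a, calls_b, truth,
                                              m_comparisons = 3)$p_adjusted)
  # large discordant counts switch to the continuity-corrected chi-square
  ca <- rep(c(1, 0), c(30, 10)); cb <- rep(c(0, 1), c(30, 10))
  rr <- mcnemar_bonferroni(ca, cb, rep(1, 40))
  expect_equal(rr$method, "chi-squared")
  expect_equal(rr$p, stats::pchisq((abs(30 - 10) - 1)^2 / 40, 1,
                                   lower.tail = FALSE))
})

test_that("cross-validation partitions evenly and ranks separable data", {
  t <- make_feature_table(120, informative = c(s = 8), noise_features = 2,
                          seed = 8)
  df <- as.data.frame(preprocess_features(t)$imputed)
  builder <- function(tr) lvh_tree(lvh ~ s + noise1 + noise2, tr,
                                   minCases = 5)
  cv <- crossvalidate(df, builder, k = 10, seed = 2)
  expect_gte(cv$pooled$accuracy, 0.95)
  expect_equal(nrow(cv$folds), 10)
  # fold sizes differ by at most one
  set.seed(2)
  fold <- sample(rep_len(seq_len(10), nrow(df)))
  expect_lte(diff(range(table(fold))), 1)
  expect_error(crossvalidate(df, builder, k = 1), "k must be")
  # label-permuted data: pooled AUC hovers at chance
  aucs <- vapply(1:10, function(i) {
    set.seed(100 + i)
    dfp <- df
    dfp$lvh <- sample(dfp$lvh)
    crossvalidate(dfp, function(tr) lvh_tree(lvh ~ s + noise1 + noise2, tr,
                                             minCases = 10),
                  k = 5, seed = i)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("CCR tables stratify correctly and conserve overall accuracy", {
  # 41-patient stratum with 34 correct
  calls <- c(rep(1, 34), rep(0, 7))
  truth <- rep(1, 41)
  r <- ccr_table(calls, truth, rep("normal", 41))
  expect_equal(r$ccr, 100 * 34 / 41, tolerance = 1e-9)
  expect_equal(round(r$ccr, 1), 82.9)
  # all-correct stratum
  expect_equal(ccr_table(1, 1, "x")$ccr, 100)
  # weighted CCR reproduces overall accuracy; empty stratum warns
  set.seed(3)
  calls <- rbinom(100, 1, 0.5); truth <- rbinom(100, 1, 0.5)
  strata <- factor(sample(c("a", "b", "c"), 100, replace = TRUE),
                   levels = c("a", "b", "c", "d"))
  expect_warning(tab <- ccr_table(calls, truth, strata), "empty")
  expect_equal(sum(tab$ccr / 100 * tab$n) / sum(tab$n),
               mean(calls == truth), tolerance = 1e-12)
})

test_that("arcsine power calculation matches the published example", {
  expect_equal(power_two_proportions(0.30, 0.40, 0.05, 0.80), 178)
  # doubling the effect quarters n (up to ceiling)
  n1 <- power_two_proportions(0.30, 0.40)
  h <- 2 * asin(sqrt(0.4)) - 2 * asin(sqrt(0.3))
  p2 <- sin(asin(sqrt(0.3)) + h)^2  # doubles h relative to p1
  n2 <- power_two_proportions(0.30, p2)
  expect_lte(abs(n2 - ceiling((n1 - 1) / 4)), 1)
  # near-equal proportions: astronomically large but finite
  huge <- power_two_proportions(0.5, 0.5001)
  expect_true(is.finite(huge) && huge > 1e6)
  expect_error(power_two_proportions(0.4, 0.4), "differ")
})
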