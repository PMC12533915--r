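#' Confusion counts from paired calls and truth
#'
#' @param calls 0/1 predicted calls.
#' @param truth 0/1 true labels.
#' @return object of class `confusion_counts`: named integer vector
#'   `TP, FP, FN, TN`.
#' @export
confusion_counts <- function(calls, truth) {
  stopifnot(length(calls) == length(truth),
            all(calls %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(c(TP = sum(calls == 1 & truth == 1),
              FP = sum(calls == 1 & truth == 0),
              FN = sum(calls == 0 & truth == 1),
              TN = sum(calls == 0 & truth == 0)),
            class = "confusion_counts")
}

#' Invert printed sensitivity/specificity to integer confusion counts
#'
#' Given a reported sensitivity and specificity (percent) and the known
#' class sizes, reconstructs the (unique) integer confusion matrix whose
#' rates round to the printed values.
#'
#' @param sens_pct,spec_pct printed sensitivity and specificity (percent).
#' @param n_pos,n_neg class sizes.
#' @return a `confusion_counts` object.
#' @export
reconstruct_confusion <- function(sens_pct, spec_pct, n_pos, n_neg) {
  tp <- round(sens_pct / 100 * n_pos)
  tn <- round(spec_pct / 100 * n_neg)
  structure(c(TP = as.integer(tp), FP = as.integer(n_neg - tn),
              FN = as.integer(n_pos - tp), TN = as.integer(tn)),
            class = "confusion_counts")
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  d <- 1 + z^2 / n
  c(lower = (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / d,
    upper = (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / d)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy (with an exact Clopper-Pearson 95% CI by default, or a Wilson
#' interval), sensitivity, specificity, positive and negative predictive
#' values and F1 (`2TP / (2TP + FP + FN)`). A metric whose denominator is
#' zero is `NA` (undefined), not zero.
#'
#' @param counts a `confusion_counts` object, or TP (with `fp`, `fn`, `tn`).
#' @param fp,fn,tn individual counts when `counts` is given as TP.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return object of class `eval_report` (a list of proportions in `[0,1]`
#'   plus the counts).
#' @export
confusion_metrics <- function(counts, fp = NULL, fn = NULL, tn = NULL,
                              ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(c(TP = counts, FP = fp, FN = fn, TN = tn),
                        class = "confusion_counts")
  }
  k <- as.numeric(counts)
  names(k) <- names(counts)
  total <- sum(k)
  if (total <= 0) stop("all confusion counts are zero")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  correct <- k[["TP"]] + k[["TN"]]
  ci <- if (ci_method == "clopper-pearson")
    clopper_pearson(correct, total) else wilson_interval(correct, total)
  structure(list(
    counts = counts,
    accuracy = correct / total,
    accuracy_ci = ci,
    sensitivity = rate(k[["TP"]], k[["TP"]] + k[["FN"]]),
    specificity = rate(k[["TN"]], k[["TN"]] + k[["FP"]]),
    ppv = rate(k[["TP"]], k[["TP"]] + k[["FP"]]),
    npv = rate(k[["TN"]], k[["TN"]] + k[["FN"]]),
    f1 = rate(2 * k[["TP"]], 2 * k[["TP"]] + k[["FP"]] + k[["FN"]])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", 100 * v)
  cat(sprintf("Acc %s%% (95%% CI %s-%s)  Se %s%%  Sp %s%%  PPV %s%%  NPV %s%%  F1 %s\n",
              pct(x$accuracy), pct(x$accuracy_ci[["lower"]]),
              pct(x$accuracy_ci[["upper"]]), pct(x$sensitivity),
              pct(x$specificity), pct(x$ppv), pct(x$npv),
              if (is.na(x$f1)) "NA" else sprintf("%.3f", x$f1)))
  invisible(x)
}

# placement values of the DeLong decomposition
delong_placements <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1L))
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1L))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong comparison of two correlated ROC curves
#'
#' AUCs are Mann-Whitney statistics with half credit for ties; their
#' difference is tested with the DeLong variance built from per-case
#' placement values, giving a two-sided normal p-value. Both score vectors
#' must be paired on the same patients.
#'
#' @param scores_a,scores_b continuous scores of the two classifiers.
#' @param labels 0/1 truth, both classes present.
#' @return list `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= 0 || d == 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p, var_diff = var_diff)
}

#' AUC of one score vector (DeLong/Mann-Whitney)
#' @param scores continuous scores.
#' @param labels 0/1 truth.
#' @return AUC in `[0,1]`.
#' @export
auc_mw <- function(scores, labels) delong_placements(scores, labels)$auc

#' McNemar comparison of two paired classifiers, Bonferroni adjusted
#'
#' Counts the discordant pairs (one classifier correct where the other is
#' wrong); uses the exact two-sided binomial test when there are fewer than
#' 25 discordant pairs and the continuity-corrected chi-square otherwise;
#' the Bonferroni-adjusted p-value `min(1, p * m)` is truncated at 1.
#' Zero discordant pairs give p = 1 (not an error).
#'
#' @param calls_a,calls_b 0/1 calls of the two classifiers.
#' @param truth 0/1 labels.
#' @param m_comparisons Bonferroni multiplier (default 1).
#' @return list `b`, `c` (discordant counts), `p`, `p_adjusted`, `method`.
#' @export
mcnemar_bonferroni <- function(calls_a, calls_b, truth, m_comparisons = 1L) {
  stopifnot(length(calls_a) == length(truth),
            length(calls_b) == length(truth))
  ok_a <- calls_a == truth
  ok_b <- calls_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  nd <- b + cc
  if (nd == 0) {
    p <- 1
    method <- "none"
  } else if (nd < 25L) {
    p <- stats::binom.test(b, nd, 0.5)$p.value
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-squared"
  }
  list(b = b, c = cc, p = p,
       p_adjusted = min(1, p * m_comparisons), method = method)
}

#' k-fold cross-validation of a model builder
#'
#' Seeded fold assignment (fold sizes differing by at most one); for each
#' fold the builder is fit on the remaining folds and applied to the held-out
#' fold. Predictions are pooled into one confusion matrix; per-fold metrics
#' and the pooled AUC are also returned.
#'
#' @param t a [feature_table()] (or plain data.frame with the label column).
#' @param builder `function(train_df)` returning an object with a
#'   [predict()] method giving probabilities (`type = "prob"`).
#' @param k folds (default 10, >= 2, at most the minority-class count).
#' @param seed integer seed for fold assignment.
#' @param label label column name.
#' @return list `pooled` ([confusion_metrics()]), `auc`, `folds`
#'   (data.frame of per-fold accuracy/sensitivity/specificity), `calls`,
#'   `probs` (in row order of `t`).
#' @export
crossvalidate <- function(t, builder, k = 10L, seed = 1L, label = "lvh") {
  df <- as.data.frame(t)
  y <- df[[label]]
  if (k < 2L) stop("k must be >= 2")
  if (k > min(table(y))) stop("k exceeds the minority class count")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(df)))
  probs <- numeric(nrow(df))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- builder(df[!hold, , drop = FALSE])
    probs[hold] <- predict(fit, df[hold, , drop = FALSE], type = "prob")
    cm <- confusion_metrics(confusion_counts(as.integer(probs[hold] >= 0.5),
                                             y[hold]))
    per_fold[[f]] <- data.frame(fold = f, accuracy = cm$accuracy,
                                sensitivity = cm$sensitivity,
                                specificity = cm$specificity)
  }
  calls <- as.integer(probs >= 0.5)
  list(pooled = confusion_metrics(confusion_counts(calls, y)),
       auc = auc_mw(probs, y),
       folds = do.call(rbind, per_fold),
       calls = calls, probs = probs)
}

#' Correct-classification rate per stratum
#'
#' For strata wholly without LVH the CCR equals the in-stratum specificity;
#' for all-LVH strata it equals the in-stratum sensitivity. Empty strata
#' are omitted with a warning. CCR weighted by stratum sizes reproduces
#' overall accuracy.
#'
#' @param calls 0/1 calls.
#' @param truth 0/1 labels.
#' @param strata factor or character stratum per patient (no missing).
#' @return data.frame `stratum`, `n`, `correct`, `ccr` (percent).
#' @export
ccr_table <- function(calls, truth, strata) {
  stopifnot(length(calls) == length(truth), length(strata) == length(truth))
  if (anyNA(strata)) stop("strata must cover all patients")
  strata <- as.factor(strata)
  lev <- levels(strata)
  empty <- lev[!lev %in% unique(as.character(strata))]
  if (length(empty))
    warning("omitting empty stratum(s): ", paste(empty, collapse = ", "))
  ok <- calls == truth
  out <- lapply(setdiff(lev, empty), function(s) {
    idx <- strata == s
    data.frame(stratum = s, n = sum(idx), correct = sum(ok[idx]),
               ccr = 100 * sum(ok[idx]) / sum(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample size for comparing two proportions (arcsine effect size)
#'
#' Cohen's effect `h = 2 asin(sqrt(p2)) - 2 asin(sqrt(p1))`; the per-group
#' size is `ceiling((z[1 - alpha/2] + z[power])^2 / h^2)`.
#'
#' @param p1,p2 the two proportions (distinct, in (0, 1)).
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @return integer n per group.
#' @export
power_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  if (p1 == p2) stop("p1 and p2 must differ (infinite sample size)")
  h <- 2 * asin(sqrt(p2)) - 2 * asin(sqrt(p1))
  ceiling((stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / h^2)
}
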