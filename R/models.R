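#' Published predictor sets of the three tree criteria
#'
#' The pinned whitelists (5 VCG-only predictors; 6 combined VCG+ECG
#' predictors, also used by the specificity-tuned variant), named with the
#' package's feature-name contract.
#' @export
PINNED_PREDICTORS <- list(
  vcg = c("GAV_K", "RangeAngR", "PMagP2", "POrbFrqD5", "Vel_Min_Kf_T"),
  vcg_ecg = c("Ang_Term_Num", "T_AREA_DI", "ECG21", "QRSMagP1", "TVelQ5",
              "QRSMagPf9"),
  vcg_ecg_sp = c("Ang_Term_Num", "T_AREA_DI", "ECG21", "QRSMagP1", "TVelQ5",
                 "QRSMagPf9"))

#' Build the three interpretable Echo-LVH tree criteria
#'
#' Reproducible pipeline from a labeled feature table to three decision-tree
#' criteria: (i) a VCG-only model on the lasso-selected VCG features, (ii) a
#' combined model on the union of the VCG and ECG selections, and (iii) a
#' specificity-tuned variant of (ii) with a false-positive cost multiplier
#' chosen by grid search to maximise cross-validated specificity subject to
#' sensitivity >= 0.55. `minCases` and winnowing are optimised by grid
#' search on cross-validated AUC within the training split. Trees are fit on
#' z-scored data and report thresholds in original units. With
#' `pinned = TRUE` the lasso step is bypassed and the whitelists are exactly
#' the published 5/6/6 predictor sets (the table must contain those
#' columns).
#'
#' @param t a [feature_table()]; a 70/30 `split` column is added (seeded)
#'   when absent.
#' @param seed integer seed governing the split, fold assignments and any
#'   other randomness.
#' @param pinned use the published predictor whitelists instead of lasso.
#' @param minCases_grid,cost_grid grid-search ranges.
#' @param cv_k folds for the internal grid-search cross-validation.
#' @param min_sensitivity feasibility bound for the specificity-tuned model.
#' @return object of class `lvh_model_set`: list with `models` (named list
#'   of [lvh_tree()]), `whitelists`, `configs`, `table` (with its split),
#'   `scaling` and `seed`.
#' @export
build_lvh_models <- function(t, seed = 1L, pinned = FALSE,
                             minCases_grid = c(2L, 5L, 10L, 20L),
                             cost_grid = c(1, 1.5, 2, 3),
                             cv_k = 5L, min_sensitivity = 0.55) {
  g <- attr(t, "groups")
  if (!all(c("VCG", "ECG") %in% g))
    stop("table must carry both VCG and ECG feature groups")
  if (!"split" %in% names(t)) t <- assign_split(t, 0.7, seed = seed)
  pp <- preprocess_features(t)
  if (pinned) {
    wl <- PINNED_PREDICTORS
    missing_cols <- setdiff(unique(unlist(wl)), names(pp$imputed))
    if (length(missing_cols))
      stop("pinned mode needs columns: ", paste(missing_cols, collapse = ", "))
  } else {
    sel_vcg <- lasso_select(pp$scaled, "VCG", k = cv_k, seed = seed)
    sel_ecg <- lasso_select(pp$scaled, "ECG", k = cv_k, seed = seed + 1L)
    if (!length(sel_vcg)) stop("lasso selected no VCG features")
    wl <- list(vcg = sel_vcg,
               vcg_ecg = union(sel_vcg, sel_ecg),
               vcg_ecg_sp = union(sel_vcg, sel_ecg))
  }
  train_scaled <- as.data.frame(pp$scaled)[pp$scaled$split == "train", ]
  train_imp <- as.data.frame(pp$imputed)[pp$imputed$split == "train", ]
  label <- attr(t, "label")

  tune <- function(whitelist, cost_fp = 1) {
    best <- NULL
    for (mc in minCases_grid) for (wn in c(FALSE, TRUE)) {
      cv <- crossvalidate(
        train_imp,
        function(df) lvh_tree(stats::reformulate(whitelist, label), df,
                              minCases = mc, winnow = wn, cost_fp = cost_fp),
        k = cv_k, seed = seed, label = label)
      cand <- list(minCases = mc, winnow = wn, auc = cv$auc,
                   sens = cv$pooled$sensitivity,
                   spec = cv$pooled$specificity)
      if (is.null(best) || cand$auc > best$auc + 1e-9) best <- cand
    }
    best
  }

  fit_final <- function(whitelist, cfg, cost_fp = 1) {
    lvh_tree(stats::reformulate(whitelist, label), train_scaled,
             minCases = cfg$minCases, winnow = cfg$winnow,
             cost_fp = cost_fp, scaling = pp$scaling)
  }

  cfg_vcg <- tune(wl$vcg)
  cfg_comb <- tune(wl$vcg_ecg)
  m_vcg <- fit_final(wl$vcg, cfg_vcg)
  m_comb <- fit_final(wl$vcg_ecg, cfg_comb)

  # specificity-tuned variant: pick the false-positive cost maximising CV
  # specificity subject to the sensitivity floor
  best_sp <- NULL
  for (cfp in cost_grid) {
    cv <- crossvalidate(
      train_imp,
      function(df) lvh_tree(stats::reformulate(wl$vcg_ecg_sp, label), df,
                            minCases = cfg_comb$minCases,
                            winnow = cfg_comb$winnow, cost_fp = cfp),
      k = cv_k, seed = seed, label = label)
    feasible <- !is.na(cv$pooled$sensitivity) &&
      cv$pooled$sensitivity >= min_sensitivity
    cand <- list(cost_fp = cfp, spec = cv$pooled$specificity,
                 sens = cv$pooled$sensitivity, feasible = feasible)
    better <- if (is.null(best_sp)) TRUE
      else if (feasible && !best_sp$feasible) TRUE
      else if (feasible == best_sp$feasible)
        isTRUE(cand$spec > best_sp$spec + 1e-9) else FALSE
    if (better) best_sp <- cand
  }
  m_sp <- fit_final(wl$vcg_ecg_sp,
                    list(minCases = cfg_comb$minCases,
                         winnow = cfg_comb$winnow),
                    cost_fp = best_sp$cost_fp)

  structure(list(models = list(vcg = m_vcg, vcg_ecg = m_comb,
                               vcg_ecg_sp = m_sp),
                 whitelists = wl,
                 configs = list(vcg = cfg_vcg, vcg_ecg = cfg_comb,
                                vcg_ecg_sp = c(cfg_comb[c("minCases", "winnow")],
                                               best_sp)),
                 table = t, scaling = pp$scaling, imputed = pp$imputed,
                 seed = seed, pinned = pinned),
            class = "lvh_model_set")
}

#' @export
print.lvh_model_set <- function(x, ...) {
  cat("Echo-LVH tree criteria (seed", x$seed,
      if (x$pinned) ", pinned predictors" else "", ")\n")
  for (nm in names(x$models)) {
    cat(sprintf("\n== %s (%d predictors) ==\n", nm,
                length(x$whitelists[[nm]])))
    print(x$models[[nm]])
  }
  invisible(x)
}

#' Evaluate a model set on one split of its table
#'
#' @param mset an [build_lvh_models()] result.
#' @param split `"test"` or `"train"`.
#' @return data.frame, one row per model: confusion counts, accuracy (with
#'   CI), sensitivity, specificity, PPV, NPV, F1 and AUC, rates in percent.
#' @export
model_performance <- function(mset, split = c("test", "train")) {
  split <- match.arg(split)
  df <- as.data.frame(mset$imputed)
  df <- df[df$split == split, , drop = FALSE]
  y <- df$lvh
  rows <- lapply(names(mset$models), function(nm) {
    pr <- predict(mset$models[[nm]], df, type = "both")
    cm <- confusion_metrics(confusion_counts(pr$call, y))
    data.frame(model = nm,
               TP = cm$counts[["TP"]], FP = cm$counts[["FP"]],
               FN = cm$counts[["FN"]], TN = cm$counts[["TN"]],
               accuracy = 100 * cm$accuracy,
               acc_lo = 100 * cm$accuracy_ci[["lower"]],
               acc_hi = 100 * cm$accuracy_ci[["upper"]],
               sensitivity = 100 * cm$sensitivity,
               specificity = 100 * cm$specificity,
               ppv = 100 * cm$ppv, npv = 100 * cm$npv, f1 = cm$f1,
               auc = auc_mw(pr$prob, y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
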