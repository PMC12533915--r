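sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Impute and z-scale the feature columns of a table
#'
#' Per feature column: the skewness of the non-missing values is computed;
#' missing values are imputed by the mean when the distribution is roughly
#' symmetric (|skewness| <= 1) and by the median otherwise; the column is
#' then z-scored using the *training-split* mean and standard deviation so
#' the test split never informs the scaling. Zero-variance columns are
#' excluded with a warning. The returned scaling parameters invert scaled
#' thresholds back to original units (`x = z * scale + center`).
#'
#' @param t a [feature_table()]; when it has a `split` column, statistics are
#'   computed on the `"train"` rows only.
#' @param impute_skew absolute skewness above which the median imputes
#'   (default 1).
#' @return list with elements `scaled` (z-scored [feature_table()]),
#'   `imputed` (imputed table in original units) and `scaling` (data.frame
#'   `feature`, `center`, `scale`, `impute_value`, `method`).
#' @export
preprocess_features <- function(t, impute_skew = 1) {
  g <- attr(t, "groups")
  train <- if ("split" %in% names(t)) t$split == "train" else rep(TRUE, nrow(t))
  if (!any(train)) stop("no training rows")
  drop <- character(0)
  sc <- list()
  imputed <- t
  for (nm in names(g)) {
    x <- t[[nm]]
    tr <- x[train]
    if (sum(!is.na(tr)) < 2L) { drop <- c(drop, nm); next }
    sk <- sample_skewness(tr)
    method <- if (abs(sk) <= impute_skew) "mean" else "median"
    fill <- if (method == "mean") mean(tr, na.rm = TRUE)
            else stats::median(tr, na.rm = TRUE)
    x[is.na(x)] <- fill
    ctr <- mean(x[train])
    scl <- stats::sd(x[train])
    if (!is.finite(scl) || scl == 0) { drop <- c(drop, nm); next }
    imputed[[nm]] <- x
    sc[[nm]] <- data.frame(feature = nm, center = ctr, scale = scl,
                           impute_value = fill, method = method,
                           stringsAsFactors = FALSE)
  }
  if (length(drop)) {
    warning("excluding constant or empty feature column(s): ",
            paste(drop, collapse = ", "))
    keep <- setdiff(names(imputed), drop)
    imputed <- imputed[, keep, drop = FALSE]
    g <- g[setdiff(names(g), drop)]
  }
  scaling <- do.call(rbind, sc)
  scaled <- imputed
  for (nm in scaling$feature)
    scaled[[nm]] <- (imputed[[nm]] - scaling$center[scaling$feature == nm]) /
      scaling$scale[scaling$feature == nm]
  lbl <- attr(t, "label")
  list(scaled = feature_table(as.data.frame(scaled), g, label = lbl),
       imputed = feature_table(as.data.frame(imputed), g, label = lbl),
       scaling = scaling)
}

#' Lasso feature pruning within one signal family
#'
#' L1-penalized logistic regression of the label on one group's feature
#' columns, with the penalty chosen to maximise k-fold cross-validated AUC
#' on the training split; features with nonzero coefficients at the chosen
#' penalty are returned. Fold assignment is seeded, so selection is
#' deterministic given the seed.
#'
#' @param t a preprocessed (complete) [feature_table()]; rows with
#'   `split == "test"` are ignored when a split column is present.
#' @param group `"VCG"` or `"ECG"`.
#' @param k cross-validation folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return character vector of selected feature names (possibly empty).
#' @export
lasso_select <- function(t, group, k = 5L, seed = 1L) {
  vars <- feature_names(t, group)
  if (!length(vars)) stop("no features tagged ", group)
  train <- if ("split" %in% names(t)) t$split == "train" else rep(TRUE, nrow(t))
  df <- as.data.frame(t)[train, , drop = FALSE]
  if (nrow(df) < 20L) stop("lasso selection needs >= 20 training rows")
  y <- df[[attr(t, "label")]]
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(df[, vars, drop = FALSE])
  if (anyNA(x)) stop("lasso selection requires complete features (preprocess first)")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(k), nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          type.measure = "auc", foldid = foldid)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
  names(beta)[beta != 0]
}
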