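entropy2 <- function(a, b) {
  s <- a + b
  if (s <= 0) return(0)
  p <- c(a, b) / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Best binary threshold split of x for binary labels. Candidate thresholds
# are midpoints between consecutive distinct values; both children must
# contain at least minCases rows. Returns NULL or list(threshold, gain,
# ratio).
best_split <- function(x, y, minCases, allow_zero = FALSE) {
  n <- length(x)
  if (n < 2L * minCases) return(NULL)
  o <- order(x)
  xo <- x[o]; yo <- y[o]
  cp <- cumsum(yo == 1L)
  cn <- cumsum(yo == 0L)
  W <- cp[n] + cn[n]
  hp <- entropy2(cp[n], cn[n])
  cuts <- which(diff(xo) > 0)
  cuts <- cuts[cuts >= minCases & (n - cuts) >= minCases]
  if (!length(cuts)) return(NULL)
  best <- NULL
  for (i in cuts) {
    wl <- cp[i] + cn[i]
    wr <- W - wl
    if (wl <= 0 || wr <= 0) next
    hl <- entropy2(cp[i], cn[i])
    hr <- entropy2(cp[n] - cp[i], cn[n] - cn[i])
    gain <- hp - (wl * hl + wr * hr) / W
    si <- entropy2(wl, wr)
    if (si <= 0) next
    ratio <- gain / si
    min_gain <- if (allow_zero) -1e-10 else 1e-10
    if (gain > min_gain && (is.null(best) || ratio > best$ratio + 1e-12))
      best <- list(threshold = unname((xo[i] + xo[i + 1L]) / 2),
                   gain = gain, ratio = ratio)
  }
  best
}

# Clopper-Pearson style upper confidence bound on the error rate, the
# pessimistic-error device of the C4.5 lineage (confidence factor cf).
pessimistic_ucb <- function(E, N, cf = 0.25) {
  if (N <= 0) return(0)
  if (E >= N) return(1)
  stats::qbeta(1 - cf, E + 1, N - E)
}

#' Interpretable gain-ratio decision tree for Echo-LVH
#'
#' Top-down induction of a binary classification tree in the C4.5/C5.0
#' lineage: splits are binary thresholds on continuous predictors chosen to
#' maximise the information gain ratio; growth stops at pure nodes or nodes
#' smaller than `2 * minCases`; the grown tree is pruned bottom-up by
#' pessimistic-error estimates (confidence factor `cf`). An asymmetric
#' misclassification cost `cost_fp` (>= 1) weights the negative class so
#' that false positives are penalised, biasing leaf labels toward higher
#' specificity. Optional winnowing drops predictors whose best univariate
#' split has zero gain before induction.
#'
#' When the model is fit on z-scored data, pass the `scaling` parameters of
#' [preprocess_features()]: split thresholds are stored and reported in
#' original units, and [predict.lvh_tree()] then expects original-unit data.
#'
#' @param formula model formula, e.g. `lvh ~ .` or `lvh ~ GAV_K + RangeAngR`.
#' @param data data.frame with a 0/1 response and numeric predictors
#'   (complete cases; impute first).
#' @param minCases minimum rows per child node (default 2).
#' @param winnow drop zero-gain predictors before induction (default FALSE).
#' @param cost_fp false-positive cost multiplier (>= 1; false negatives cost
#'   1).
#' @param cf pruning confidence factor (default 0.25); `cf = 1` disables
#'   pruning.
#' @param scaling optional scaling data.frame from [preprocess_features()].
#' @param prune apply pessimistic pruning (default TRUE).
#' @param max_depth growth depth cap (default 30; far beyond any pruned
#'   clinical tree, it only bounds degenerate zero-gain chains).
#' @return an object of class `lvh_tree`.
#' @export
lvh_tree <- function(formula, data, minCases = 2L, winnow = FALSE,
                     cost_fp = 1, cf = 0.25, scaling = NULL, prune = TRUE,
                     max_depth = 30L) {
  stopifnot(minCases >= 1L, cost_fp >= 1, cf > 0, cf <= 1, max_depth >= 1L)
  mf <- stats::model.frame(formula, as.data.frame(data),
                           na.action = stats::na.pass)
  y <- mf[[1L]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1)) || anyNA(y)) stop("response must be 0/1")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  vars <- attr(stats::terms(mf), "term.labels")
  if (!length(vars)) stop("no predictors")
  X <- as.matrix(mf[, vars, drop = FALSE])
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X)) stop("training predictors must be complete")
  if (winnow) {
    keep <- vapply(vars, function(v)
      !is.null(best_split(X[, v], y, minCases)), logical(1L))
    if (any(keep)) {
      vars <- vars[keep]
      X <- X[, vars, drop = FALSE]
    }
  }
  root <- grow_node(X, y, vars, minCases, max_depth, cost_fp)
  unpruned_leaves <- count_leaves(root)
  if (prune) root <- prune_node(root, cf, cost_fp)
  if (!is.null(scaling)) root <- rescale_node(root, scaling)
  model <- structure(list(root = root, predictors = vars,
                          minCases = as.integer(minCases), winnow = winnow,
                          cost_fp = cost_fp, cf = cf, threshold = 0.5,
                          scaling = scaling,
                          unpruned_leaves = unpruned_leaves,
                          units = if (is.null(scaling)) "as-trained"
                                  else "original"),
                     class = "lvh_tree")
  # training confusion, computed by routing the training rows themselves
  # (routed before rescaling semantics matter: route on the fit data)
  prob <- route_prob(if (is.null(scaling)) root else
    rescale_node(root, scaling, invert = TRUE), X)
  call <- as.integer(prob >= 0.5)
  model$training <- list(
    n = length(y),
    confusion = c(TP = sum(call == 1L & y == 1L),
                  FP = sum(call == 1L & y == 0L),
                  FN = sum(call == 0L & y == 1L),
                  TN = sum(call == 0L & y == 0L)))
  model
}

make_leaf <- function(npos, nneg, cost_fp) {
  # cost-weighted Laplace class frequencies: at cost_fp = 1 this is the
  # plain (pos + 1) / (n + 2) LVH fraction
  prob <- (npos + 1) / (npos + cost_fp * nneg + 2)
  list(type = "leaf", n = npos + nneg, npos = npos, nneg = nneg,
       prob = prob, pred = as.integer(prob >= 0.5))
}

# Splits and pruning are cost-blind (identical tree structure for every
# cost_fp); the cost only reweights leaf class frequencies, so raising it
# can flip calls positive -> negative but never the reverse.
grow_node <- function(X, y, vars, minCases, depth_left = 30L, cost_fp = 1) {
  n <- length(y)
  npos <- sum(y == 1L)
  leaf <- make_leaf(npos, n - npos, cost_fp)
  if (npos == 0L || npos == n || n < 2L * minCases || depth_left <= 0L)
    return(leaf)
  best <- NULL
  for (v in vars) {
    s <- best_split(X[, v], y, minCases)
    if (!is.null(s) && (is.null(best) || s$ratio > best$ratio + 1e-12))
      best <- c(s, list(feature = v))
  }
  if (is.null(best)) {
    # no positive-gain cut: fall back to a zero-gain split (a symmetric
    # XOR-like node has informative children despite zero marginal gain);
    # pruning removes such splits when they lead nowhere
    for (v in vars) {
      s <- best_split(X[, v], y, minCases, allow_zero = TRUE)
      if (!is.null(s) && (is.null(best) || s$ratio > best$ratio + 1e-12))
        best <- c(s, list(feature = v))
    }
  }
  if (is.null(best)) return(leaf)
  go_left <- X[, best$feature] <= best$threshold
  list(type = "split", feature = best$feature, threshold = best$threshold,
       n = n, npos = npos, nneg = n - npos,
       majority = if (sum(go_left) >= sum(!go_left)) "left" else "right",
       left = grow_node(X[go_left, , drop = FALSE], y[go_left],
                        vars, minCases, depth_left - 1L, cost_fp),
       right = grow_node(X[!go_left, , drop = FALSE], y[!go_left],
                         vars, minCases, depth_left - 1L, cost_fp))
}

count_leaves <- function(node) {
  if (node$type == "leaf") 1L
  else count_leaves(node$left) + count_leaves(node$right)
}

tree_depth <- function(node) {
  if (node$type == "leaf") 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

# pessimistic error of a (sub)tree under plain-majority labels, so the
# pruning decision is independent of the misclassification cost
subtree_error_est <- function(node, cf) {
  if (node$type == "leaf") {
    E <- min(node$npos, node$nneg)
    return(node$n * pessimistic_ucb(E, node$n, cf))
  }
  subtree_error_est(node$left, cf) + subtree_error_est(node$right, cf)
}

prune_node <- function(node, cf, cost_fp = 1) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, cf, cost_fp)
  node$right <- prune_node(node$right, cf, cost_fp)
  as_leaf_est <- node$n * pessimistic_ucb(min(node$npos, node$nneg),
                                          node$n, cf)
  if (as_leaf_est <= subtree_error_est(node, cf))
    return(make_leaf(node$npos, node$nneg, cost_fp))
  node
}

# convert split thresholds between scaled and original units
rescale_node <- function(node, scaling, invert = FALSE) {
  if (node$type == "leaf") return(node)
  i <- match(node$feature, scaling$feature)
  if (!is.na(i)) {
    node$threshold <- if (invert)
      (node$threshold - scaling$center[i]) / scaling$scale[i]
    else node$threshold * scaling$scale[i] + scaling$center[i]
  }
  node$left <- rescale_node(node$left, scaling, invert)
  node$right <- rescale_node(node$right, scaling, invert)
  node
}

route_prob <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(nd, idx) {
    if (!length(idx)) return()
    if (nd$type == "leaf") { out[idx] <<- nd$prob; return() }
    x <- X[idx, nd$feature]
    left <- x <= nd$threshold
    left[is.na(left)] <- nd$majority == "left"
    rec(nd$left, idx[left])
    rec(nd$right, idx[!left])
  }
  rec(node, seq_len(nrow(X)))
  out
}

#' Predict Echo-LVH probability and call from a fitted tree
#'
#' Rows are routed down the tree; a missing predictor value follows the
#' majority branch of its node. The probability is the Laplace-smoothed
#' LVH fraction of the reached leaf (`(pos + 1) / (n + 2)`); the binary call
#' applies the fixed 0.5 probability threshold.
#'
#' @param object an [lvh_tree()].
#' @param newdata data.frame containing the model's predictors, in the units
#'   the model reports (original units when fit with `scaling`).
#' @param type `"prob"`, `"class"`, or `"both"` (data.frame).
#' @param ... unused.
#' @return numeric vector, integer vector, or data.frame.
#' @export
predict.lvh_tree <- function(object, newdata, type = c("prob", "class", "both"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$predictors, names(newdata))
  for (nm in miss) newdata[[nm]] <- NA_real_
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  prob <- route_prob(object$root, X)
  call <- as.integer(prob >= object$threshold)
  switch(type, prob = prob, class = call,
         both = data.frame(prob = prob, call = call))
}

#' @export
print.lvh_tree <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Gain-ratio decision tree: %d leaves, depth %d (minCases=%d, cost_fp=%g%s)\n",
    count_leaves(x$root), tree_depth(x$root), x$minCases, x$cost_fp,
    if (x$winnow) ", winnowed" else ""))
  if (!is.null(x$scaling)) cat("Thresholds in original units.\n")
  print_node(x$root, "", digits)
  invisible(x)
}

print_node <- function(node, indent, digits) {
  if (node$type == "leaf") {
    cat(sprintf("%s-> %s (n=%d, LVH %d/%d, p=%.3f)\n", indent,
                if (node$pred == 1L) "LVH" else "no LVH",
                node$n, node$npos, node$n, node$prob))
    return(invisible())
  }
  cat(sprintf("%s%s <= %s:\n", indent, node$feature,
              format(node$threshold, digits = digits)))
  print_node(node$left, paste0(indent, "  "), digits)
  cat(sprintf("%s%s >  %s:\n", indent, node$feature,
              format(node$threshold, digits = digits)))
  print_node(node$right, paste0(indent, "  "), digits)
}

#' @export
summary.lvh_tree <- function(object, ...) {
  cm <- object$training$confusion
  structure(list(leaves = count_leaves(object$root),
                 unpruned_leaves = object$unpruned_leaves,
                 depth = tree_depth(object$root),
                 predictors = object$predictors,
                 config = list(minCases = object$minCases,
                               winnow = object$winnow,
                               cost_fp = object$cost_fp, cf = object$cf),
                 training_confusion = cm,
                 training_accuracy = (cm[["TP"]] + cm[["TN"]]) /
                   object$training$n),
            class = "summary.lvh_tree")
}

#' @export
print.summary.lvh_tree <- function(x, ...) {
  cat(sprintf("lvh_tree: %d leaves (unpruned %d), depth %d\n",
              x$leaves, x$unpruned_leaves, x$depth))
  cat("predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat(sprintf("minCases=%d winnow=%s cost_fp=%g cf=%g\n",
              x$config$minCases, x$config$winnow, x$config$cost_fp,
              x$config$cf))
  cat(sprintf("training accuracy %.3f; confusion TP=%d FP=%d FN=%d TN=%d\n",
              x$training_accuracy, x$training_confusion[["TP"]],
              x$training_confusion[["FP"]], x$training_confusion[["FN"]],
              x$training_confusion[["TN"]]))
  invisible(x)
}

#' Plot a fitted decision tree
#'
#' Simple dendrogram-style rendering: split nodes show `feature <= threshold`
#' (left branch true), leaves show the class call and LVH fraction.
#'
#' @param x an [lvh_tree()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.lvh_tree <- function(x, ...) {
  leaves <- count_leaves(x$root)
  depth <- tree_depth(x$root)
  graphics::plot(NULL, xlim = c(0.5, leaves + 0.5), ylim = c(-depth - 0.6, 0.4),
                 axes = FALSE, xlab = "", ylab = "", ...)
  counter <- new.env()
  counter$x <- 0
  draw <- function(node, d) {
    if (node$type == "leaf") {
      counter$x <- counter$x + 1
      graphics::text(counter$x, -d - 0.25,
                     sprintf("%s\n%d/%d",
                             if (node$pred == 1L) "LVH" else "no LVH",
                             node$npos, node$n), cex = 0.7)
      return(counter$x)
    }
    xl <- draw(node$left, d + 1)
    xr <- draw(node$right, d + 1)
    xm <- (xl + xr) / 2
    graphics::segments(c(xm, xm), c(-d, -d), c(xl, xr), c(-d - 1, -d - 1))
    graphics::text(xm, -d + 0.18,
                   sprintf("%s <= %.3g", node$feature, node$threshold),
                   cex = 0.75)
    xm
  }
  draw(x$root, 0)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#'
#' Nodes (features, thresholds in the model's reported units, leaf counts
#' and probabilities), the predictor whitelist, configuration and scaling
#' parameters are written to a JSON file readable by [read_lvh_tree()].
#'
#' @param model an [lvh_tree()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_lvh_tree <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_lvh_tree
#' @export
read_lvh_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  fix <- function(nd) {
    nd <- as.list(nd)
    if (nd$type == "split") {
      nd$left <- fix(nd$left)
      nd$right <- fix(nd$right)
    }
    nd
  }
  obj$root <- fix(obj$root)
  structure(obj, class = "lvh_tree")
}
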