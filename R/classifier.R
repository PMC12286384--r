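#' Class weights inversely proportional to class frequency
#'
#' w_v = n / (k * n_v), where n is the total sample count, k the number of
#' classes and n_v the count of class v; balanced classes get weight 1 and
#' the weights always satisfy sum(w_v * n_v) = n.
#'
#' @param labels factor/character vector of class labels, or a named table of
#'   class counts.
#' @return object of class `class_weights`: list with `weights` (named
#'   vector), `n`, `k`.
#' @export
class_weights <- function(labels) {
  cnt <- if (is.table(labels) || (!is.null(names(labels)) && is.numeric(labels))) {
    setNames(as.numeric(labels), names(labels))
  } else {
    c(table(as.character(labels)))
  }
  if (any(cnt <= 0)) stop("every class must have a positive count")
  n <- sum(cnt)
  k <- length(cnt)
  structure(list(weights = n / (k * cnt), n = n, k = k),
            class = "class_weights")
}

#' Class-weighted Gini impurity of a tree node
#'
#' G_u = 1 - sum_v w_v * p_{u,v}^2, with p_{u,v} the fraction of class-v
#' samples at the node. With all weights 1 this is the ordinary Gini index;
#' note the weight multiplies the squared proportion, so heavily weighted
#' (minority) classes lower the impurity of nodes they dominate more
#' strongly.
#'
#' @param counts named non-negative class counts at the node.
#' @param weights a [class_weights()] object, a named numeric vector, or NULL
#'   for all-ones.
#' @return impurity value.
#' @export
weighted_gini <- function(counts, weights = NULL) {
  counts <- setNames(as.numeric(counts), names(counts))
  tot <- sum(counts)
  if (tot <= 0) stop("node has no samples; impurity undefined")
  w <- if (is.null(weights)) {
    rep(1, length(counts))
  } else if (inherits(weights, "class_weights")) {
    unname(weights$weights[names(counts)])
  } else {
    unname(weights[if (!is.null(names(weights))) names(counts)
                   else seq_along(counts)])
  }
  if (anyNA(w)) stop("weights missing for some classes at this node")
  p <- counts / tot
  1 - sum(w * p^2)
}

#' Random-forest configuration
#'
#' @param n_trees trees in the final forest.
#' @param grid data.frame of hyperparameter combinations searched by
#'   cross-validation; columns `max_depth` (0 = unlimited), `mtry_rule`
#'   ("sqrt" or "log2") and `min_node` (minimum samples per leaf). Defaults
#'   to the 3 x 2 x 2 grid over depth {unlimited, 10, 20}, mtry {sqrt, log2},
#'   leaf {1, 5}.
#' @param cv_folds folds for the grid-search cross-validation.
#' @param seed integer seed making tuning and fitting reproducible.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000L, grid = NULL, cv_folds = 10L,
                      seed = 1L) {
  stopifnot(n_trees >= 1, cv_folds >= 2)
  if (is.null(grid)) {
    grid <- expand.grid(max_depth = c(0L, 10L, 20L),
                        mtry_rule = c("sqrt", "log2"),
                        min_node = c(1L, 5L),
                        stringsAsFactors = FALSE)
  }
  structure(list(n_trees = as.integer(n_trees), grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "rf_config")
}

mtry_from_rule <- function(rule, p) {
  m <- switch(rule, sqrt = floor(sqrt(p)), log2 = floor(log2(p)),
              stop("unknown mtry rule: ", rule))
  max(1L, min(p, as.integer(m)))
}

ranger_fit <- function(x, y, n_trees, max_depth, mtry_rule, min_node,
                       cw, seed) {
  # class weights enter both the split impurity and, via per-sample case
  # weights, the bootstrap and leaf composition -- the semantics of
  # class_weight in the mainstream tree libraries this mirrors
  if (!is.null(cw) && length(unique(cw[levels(y)])) == 1L) cw <- NULL
  ranger::ranger(
    x = x, y = y, num.trees = n_trees,
    mtry = mtry_from_rule(mtry_rule, ncol(x)),
    min.node.size = min_node, max.depth = max_depth,
    class.weights = if (is.null(cw)) NULL else unname(cw[levels(y)]),
    case.weights = if (is.null(cw)) NULL
                   else unname(cw[as.character(y)]),
    probability = TRUE, seed = seed, num.threads = 1L)
}

#' Fit the marker-validation random forest
#'
#' Grows a probability forest on the marker feature space with class-weighted
#' Gini impurity, after selecting hyperparameters by stratified k-fold
#' cross-validated accuracy over `config$grid` (skipped when the grid has a
#' single row). The default engine is ranger's standard class-weighted
#' impurity; `impurity = "eq6"` instead uses the bundled bagged-tree grower
#' whose split criterion is the literal weighted Gini of [weighted_gini()]
#' (practical for small problems only).
#'
#' @param x samples x features numeric matrix (the marker expression matrix).
#' @param labels class labels aligned to rows of `x`.
#' @param markers optional character vector (or list of vectors / marker_set
#'   objects) restricting and validating the feature space; an error lists
#'   any marker absent from `x`.
#' @param config an [rf_config()].
#' @param weights a [class_weights()] object or NULL for unweighted.
#' @param impurity `"standard"` (ranger) or `"eq6"` (bundled grower).
#' @return object of class `rf_fit` with the underlying model, the selected
#'   hyperparameters and the CV table.
#' @export
fit_rf <- function(x, labels, markers = NULL, config = rf_config(),
                   weights = NULL, impurity = c("standard", "eq6")) {
  impurity <- match.arg(impurity)
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  if (!is.null(markers)) {
    if (is.list(markers) && !is.data.frame(markers))
      markers <- unlist(lapply(markers, function(m)
        if (is.data.frame(m)) m$gene_id else m))
    if (is.data.frame(markers)) markers <- markers$gene_id
    markers <- unique(as.character(markers))
    missing <- setdiff(markers, colnames(x))
    if (length(missing) > 0)
      stop("marker genes absent from the expression matrix: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) " ...")
    x <- x[, markers, drop = FALSE]
  }
  cw <- if (is.null(weights)) NULL else weights$weights
  grid <- config$grid
  cv_table <- NULL
  best_row <- grid[1, , drop = FALSE]
  if (nrow(grid) > 1) {
    folds <- withr::with_seed(config$seed, make_folds(y, config$cv_folds))
    acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      hits <- 0L
      for (f in seq_along(folds)) {
        tr <- setdiff(seq_along(y), folds[[f]])
        fit <- fit_one(x[tr, , drop = FALSE], y[tr], config$n_trees,
                       grid$max_depth[gi], grid$mtry_rule[gi],
                       grid$min_node[gi], cw, config$seed + gi, impurity)
        pr <- predict_proba(fit, x[folds[[f]], , drop = FALSE])
        hits <- hits + sum(colnames(pr)[max.col(pr, "first")] ==
                             as.character(y[folds[[f]]]))
      }
      acc[gi] <- hits / length(y)
    }
    cv_table <- cbind(grid, cv_accuracy = acc)
    best_row <- grid[which.max(acc), , drop = FALSE]
  }
  model <- fit_one(x, y, config$n_trees, best_row$max_depth,
                   best_row$mtry_rule, best_row$min_node, cw,
                   config$seed, impurity)
  structure(list(model = model, impurity = impurity, levels = levels(y),
                 features = colnames(x), best = best_row,
                 cv_table = cv_table, weights = cw, config = config),
            class = "rf_fit")
}

make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  split(seq_along(y), fold)
}

fit_one <- function(x, y, n_trees, max_depth, mtry_rule, min_node, cw, seed,
                    impurity) {
  if (impurity == "standard") {
    ranger_fit(x, y, n_trees, max_depth, mtry_rule, min_node, cw, seed)
  } else {
    gini_forest(x, y, n_trees = min(n_trees, 100L),
                mtry = mtry_from_rule(mtry_rule, ncol(x)),
                min_node = min_node,
                max_depth = if (max_depth == 0) 30L else max_depth,
                weights = cw, seed = seed)
  }
}

predict_proba <- function(model, x) {
  if (inherits(model, "ranger")) {
    stats::predict(model, data = x, num.threads = 1L)$predictions
  } else {
    predict_gini_forest(model, x)
  }
}

#' Class-probability predictions from an `rf_fit`
#'
#' @param object an `rf_fit`.
#' @param newdata samples x features matrix containing the fit's features.
#' @param ... unused.
#' @return matrix of class probabilities (samples x classes).
#' @export
predict.rf_fit <- function(object, newdata, ...) {
  predict_proba(object$model, newdata[, object$features, drop = FALSE])
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' Reports accuracy, support-weighted precision/recall/F1, the confusion
#' matrix, and per-class one-vs-rest ROC curves with trapezoidal AUCs plus
#' their support-weighted average. A class absent from the test set has no
#' defined ROC; it is reported as NA and excluded from the weighted average
#' with a warning.
#'
#' @param fit an `rf_fit`.
#' @param x_test,labels_test held-out samples and labels (disjoint from
#'   training).
#' @return object of class `eval_report`.
#' @export
evaluate_classifier <- function(fit, x_test, labels_test) {
  y <- factor(as.character(labels_test), levels = fit$levels)
  prob <- predict(fit, x_test)
  pred <- factor(colnames(prob)[max.col(prob, "first")], levels = fit$levels)
  cm <- table(truth = y, predicted = pred)
  n <- length(y)
  accuracy <- sum(diag(cm)) / n
  support <- rowSums(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(support, 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wavg <- function(v) sum(v * support) / n
  auc <- setNames(rep(NA_real_, length(fit$levels)), fit$levels)
  roc_curves <- list()
  for (cl in fit$levels) {
    pos <- y == cl
    if (!any(pos) || all(pos)) next
    r <- pROC::roc(response = as.integer(pos), predictor = prob[, cl],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    auc[cl] <- as.numeric(pROC::auc(r))
    roc_curves[[cl]] <- data.frame(fpr = 1 - r$specificities,
                                   tpr = r$sensitivities)
  }
  ok <- !is.na(auc)
  if (!all(ok))
    warning("no test samples for class(es) ",
            paste(fit$levels[!ok], collapse = ", "),
            "; excluded from the weighted AUC")
  weighted_auc <- sum(auc[ok] * support[ok]) / sum(support[ok])
  structure(list(accuracy = accuracy,
                 precision = setNames(prec, fit$levels),
                 recall = setNames(rec, fit$levels),
                 f1 = setNames(f1, fit$levels),
                 weighted_precision = wavg(prec),
                 weighted_recall = wavg(rec),
                 weighted_f1 = wavg(f1),
                 auc = auc, weighted_auc = weighted_auc,
                 roc_curves = roc_curves, confusion = cm, support = support),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Multiclass evaluation on", sum(x$support), "test samples\n")
  cat(sprintf("  accuracy            %.4f\n", x$accuracy))
  cat(sprintf("  weighted precision  %.4f\n", x$weighted_precision))
  cat(sprintf("  weighted recall     %.4f\n", x$weighted_recall))
  cat(sprintf("  weighted F1         %.4f\n", x$weighted_f1))
  cat(sprintf("  weighted AUC        %.4f\n", x$weighted_auc))
  cat("  per-class AUC:\n")
  for (cl in names(x$auc))
    cat(sprintf("    %-14s %s\n", cl,
                ifelse(is.na(x$auc[cl]), "NA", sprintf("%.4f", x$auc[cl]))))
  invisible(x)
}
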