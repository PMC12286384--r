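# Small bundled CART/bagged-forest grower whose split criterion is the
# literal class-weighted Gini G_u = 1 - sum_v w_v p_{u,v}^2 (the form with
# the weight outside the squared proportion). Intended for small problems;
# the default forest engine is ranger's standard class-weighted impurity.

node_impurity <- function(counts, w) 1 - sum(w * (counts / sum(counts))^2)

best_split <- function(x, y_int, k, w, mtry, min_node) {
  p <- ncol(x)
  feats <- sample.int(p, min(mtry, p))
  best <- NULL
  n <- length(y_int)
  for (j in feats) {
    ord <- order(x[, j])
    xv <- x[ord, j]
    yv <- y_int[ord]
    left <- numeric(k)
    total <- tabulate(yv, k)
    for (i in seq_len(n - 1)) {
      left[yv[i]] <- left[yv[i]] + 1
      if (xv[i] == xv[i + 1]) next
      nl <- i; nr <- n - i
      if (nl < min_node || nr < min_node) next
      right <- total - left
      g <- (nl * node_impurity(left, w) + nr * node_impurity(right, w)) / n
      if (is.null(best) || g < best$g - 1e-12) {
        best <- list(g = g, feature = j, threshold = (xv[i] + xv[i + 1]) / 2)
      }
    }
  }
  best
}

grow_node <- function(x, y_int, k, w, mtry, min_node, max_depth, depth) {
  counts <- tabulate(y_int, k)
  if (depth >= max_depth || length(y_int) < 2 * min_node ||
      sum(counts > 0) == 1) {
    return(list(leaf = TRUE, counts = counts))
  }
  sp <- best_split(x, y_int, k, w, mtry, min_node)
  if (is.null(sp) ||
      sp$g >= node_impurity(counts, w) - 1e-12) {
    return(list(leaf = TRUE, counts = counts))
  }
  go_left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_node(x[go_left, , drop = FALSE], y_int[go_left], k, w,
                        mtry, min_node, max_depth, depth + 1),
       right = grow_node(x[!go_left, , drop = FALSE], y_int[!go_left], k, w,
                         mtry, min_node, max_depth, depth + 1))
}

#' Bagged forest with the literal weighted-Gini split criterion
#'
#' Bootstrap-aggregated CART trees grown with the impurity of
#' [weighted_gini()] (class weight outside the squared proportion). Use for
#' small marker panels; for routine fits prefer the default ranger engine of
#' [fit_rf()].
#'
#' @param x samples x features matrix.
#' @param y factor of class labels.
#' @param n_trees,mtry,min_node,max_depth forest and tree shape parameters.
#' @param weights named per-class weights (NULL = all ones).
#' @param seed integer seed.
#' @return object of class `gini_forest`.
#' @export
gini_forest <- function(x, y, n_trees = 50L, mtry = NULL, min_node = 1L,
                        max_depth = 30L, weights = NULL, seed = 1L) {
  y <- factor(y)
  k <- nlevels(y)
  y_int <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  w <- if (is.null(weights)) rep(1, k) else unname(weights[levels(y)])
  stopifnot(!anyNA(w))
  trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(nrow(x), replace = TRUE)
      grow_node(x[boot, , drop = FALSE], y_int[boot], k, w, mtry,
                min_node, max_depth, 0L)
    })
  })
  structure(list(trees = trees, levels = levels(y), weights = w,
                 features = colnames(x)),
            class = "gini_forest")
}

tree_leaf_counts <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] <= node$threshold) node$left else node$right
  }
  node$counts
}

#' @rdname gini_forest
#' @param forest a fitted `gini_forest`.
#' @param newdata samples x features matrix.
#' @return matrix of class probabilities (mean of per-tree leaf class
#'   proportions).
#' @export
predict_gini_forest <- function(forest, newdata) {
  if (!is.null(forest$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, forest$features, drop = FALSE]
  out <- matrix(0, nrow(newdata), length(forest$levels),
                dimnames = list(rownames(newdata), forest$levels))
  for (tr in forest$trees) {
    for (i in seq_len(nrow(newdata))) {
      cnt <- tree_leaf_counts(tr, newdata[i, ])
      out[i, ] <- out[i, ] + cnt / sum(cnt)
    }
  }
  out / length(forest$trees)
}
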