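#' Training configuration for the row-sparse autoencoder
#'
#' @param h bottleneck width (number of hidden nodes).
#' @param lambda non-negative penalty weight trading reconstruction loss
#'   against encoder row sparsity. The subtype defaults used on real cohorts
#'   are 1e-5 (TNBC), 1e-4 (HER2-enriched) and 1e-6 (luminal A/B).
#' @param batch_size mini-batch size for Adam.
#' @param epochs number of passes over the training split.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param lr_decay multiplicative per-epoch decay of the Adam step size
#'   (1 = constant), applied from epoch `decay_start * epochs` onward.
#'   Toy-scale full-batch fits benefit from a late anneal: constant-step Adam
#'   ends in a noise ball around the optimum whose radius scales with the
#'   step size, which blurs the encoder row norms used for scoring.
#' @param decay_start fraction of the run after which `lr_decay` kicks in.
#' @param val_fraction fraction of rows held out inside [ae_train()] for
#'   validation-loss checkpointing; 0 checkpoints on training loss.
#' @param seed integer seed, or NULL to consume the current RNG state (the
#'   mode replicate protocols use so successive runs differ).
#' @param penalty `"l21"` for the standard L2,1 norm (sum of encoder-row
#'   Euclidean norms) or `"sum_of_squares"` for the plain squared-entry sum;
#'   feature ranking is identical under both.
#' @param use_bias include bias vectors (off by default: the encoder and
#'   decoder are pure matrix products through ReLU).
#' @param nonneg_init draw initial weights from the non-negative half of the
#'   Glorot-uniform range. With non-negative inputs this starts every ReLU
#'   unit in its active region, avoiding dead hidden units at small widths.
#' @param lambda_warmup fraction of the run over which the penalty weight is
#'   ramped linearly from 0 to `lambda` (0 = full penalty from the start).
#'   Warming the penalty up lets the network first learn a dense
#'   reconstruction in which every informative gene holds encoder weight;
#'   the subsequent ramp then prunes rows by their reconstruction value,
#'   which is far less sensitive to the random initialisation than growing
#'   a sparse solution from scratch.
#' @param init_scale multiplier on the Glorot range of the initial weights;
#'   values below 1 start the network in the small-weight regime where
#'   gradient dynamics align to the leading variance directions in order.
#' @param b1_init constant initial value of the hidden bias (only with
#'   `use_bias = TRUE`). A positive value starts every hidden ReLU unit in
#'   its active region, which counters permanent unit death at small widths;
#'   0 keeps the conventional zero-bias start.
#' @return list of class `ae_config`.
#' @export
ae_config <- function(h = 500L, lambda = 1e-6, batch_size = 64L,
                      epochs = 35L, learning_rate = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, epsilon = 1e-7, lr_decay = 1,
                      decay_start = 0.7, val_fraction = 0.2,
                      seed = NULL, penalty = c("l21", "sum_of_squares"),
                      use_bias = FALSE, nonneg_init = FALSE, b1_init = 0,
                      init_scale = 1, lambda_warmup = 0) {
  penalty <- match.arg(penalty)
  stopifnot(h >= 1, lambda >= 0, batch_size >= 1, epochs >= 1,
            val_fraction >= 0, val_fraction < 1, lr_decay > 0, lr_decay <= 1,
            decay_start >= 0, decay_start <= 1)
  structure(list(h = as.integer(h), lambda = lambda,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 lr_decay = lr_decay, decay_start = decay_start,
                 val_fraction = val_fraction, seed = seed, penalty = penalty,
                 use_bias = use_bias, nonneg_init = nonneg_init,
                 b1_init = b1_init, init_scale = init_scale,
                 lambda_warmup = lambda_warmup),
            class = "ae_config")
}

#' Initialise autoencoder weights
#'
#' Glorot-uniform initialisation of the d x h encoder matrix W1 and the
#' h x d decoder matrix W2.
#'
#' @param d input dimension (number of genes).
#' @param h bottleneck width; must satisfy h < d.
#' @param seed integer seed for reproducible draws, or NULL to use the
#'   current RNG state.
#' @param gene_ids optional gene identifiers stored on the model.
#' @param use_bias include zero-initialised bias vectors.
#' @return object of class `ae_model` with elements `W1`, `W2`, `d`, `h`.
#' @export
ae_init <- function(d, h, seed = NULL, gene_ids = NULL, use_bias = FALSE) {
  d <- as.integer(d); h <- as.integer(h)
  if (h < 1 || h >= d) stop("need 1 <= h < d (got h = ", h, ", d = ", d, ")")
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  with_seed_or_state(seed, {
    m <- list(W1 = glorot(d, h), W2 = glorot(h, d), d = d, h = h,
              gene_ids = gene_ids, use_bias = use_bias)
    if (use_bias) {
      m$b1 <- numeric(h)
      m$b2 <- numeric(d)
    }
    structure(m, class = "ae_model")
  })
}

#' Autoencoder forward pass
#'
#' Reconstruction ReLU(ReLU(X W1) W2); the bottleneck activation ReLU(X W1)
#' is the compressed representation.
#'
#' @param x numeric matrix n x d (rows are samples).
#' @param model an `ae_model`.
#' @param detail return pre-activations and hidden layer too (internal use).
#' @return reconstruction matrix n x d (or a list when `detail = TRUE`).
#' @export
ae_forward <- function(x, model, detail = FALSE) {
  stopifnot(inherits(model, "ae_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d)
    stop("input has ", ncol(x), " columns; model expects ", model$d)
  z1 <- x %*% model$W1
  if (isTRUE(model$use_bias)) z1 <- sweep(z1, 2, model$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% model$W2
  if (isTRUE(model$use_bias)) z2 <- sweep(z2, 2, model$b2, `+`)
  xhat <- pmax(z2, 0)
  if (detail) list(z1 = z1, a1 = a1, z2 = z2, xhat = xhat) else xhat
}

#' L2,1 norm of a matrix
#'
#' Sum over rows of the row-wise Euclidean norm; penalising it drives entire
#' rows to zero (row sparsity), which is what makes the encoder usable for
#' feature selection.
#'
#' @param w numeric matrix.
#' @return non-negative scalar; zero iff `w` is all zeros.
#' @export
l21_norm <- function(w) {
  if (!is.matrix(w)) w <- matrix(w, nrow = 1)
  sum(sqrt(rowSums(w^2)))
}

penalty_value <- function(w, penalty) {
  if (penalty == "l21") l21_norm(w) else sum(w^2)
}

penalty_grad <- function(w, penalty) {
  if (penalty == "l21") {
    rn <- sqrt(rowSums(w^2))
    scale <- ifelse(rn > 0, 1 / rn, 0)  # subgradient 0 on zero rows
    w * scale
  } else {
    2 * w
  }
}

#' Autoencoder training objective
#'
#' Mean squared reconstruction error scaled as 1/(2n) times the squared
#' Frobenius norm of (X - X^), plus `lambda` times the encoder penalty.
#'
#' @param x n x d matrix of scaled expression values.
#' @param model an `ae_model`.
#' @param lambda penalty weight.
#' @param penalty `"l21"` or `"sum_of_squares"`.
#' @return non-negative scalar.
#' @export
ae_objective <- function(x, model, lambda = 0,
                         penalty = c("l21", "sum_of_squares")) {
  penalty <- match.arg(penalty)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("objective undefined on an empty sample set")
  r <- x - ae_forward(x, model)
  sum(r^2) / (2 * nrow(x)) + lambda * penalty_value(model$W1, penalty)
}

#' Analytic gradient of the training objective
#'
#' Backpropagation through the two ReLU layers plus the penalty subgradient
#' (taken as 0 on zero rows and at ReLU kinks).
#'
#' @inheritParams ae_objective
#' @return list with matrices `W1` and `W2` (and `b1`, `b2` when the model
#'   has biases) matching the model's shapes.
#' @export
ae_gradient <- function(x, model, lambda = 0,
                        penalty = c("l21", "sum_of_squares")) {
  penalty <- match.arg(penalty)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- nrow(x)
  f <- ae_forward(x, model, detail = TRUE)
  d_xhat <- (f$xhat - x) / n            # d/dxhat of (1/2n)||x - xhat||^2
  d_z2 <- d_xhat * (f$z2 > 0)
  g_w2 <- crossprod(f$a1, d_z2)
  d_a1 <- d_z2 %*% t(model$W2)
  d_z1 <- d_a1 * (f$z1 > 0)
  g_w1 <- crossprod(x, d_z1) + lambda * penalty_grad(model$W1, penalty)
  out <- list(W1 = g_w1, W2 = g_w2)
  if (isTRUE(model$use_bias)) {
    out$b1 <- colSums(d_z1)
    out$b2 <- colSums(d_z2)
  }
  out
}

#' Train the row-sparse autoencoder
#'
#' Mini-batch Adam on the penalised reconstruction objective. An internal
#' train/validation row split (`val_fraction`) is drawn once per call; the
#' validation loss is monitored at every epoch and the weights of the latest
#' best model (earliest epoch on ties) are checkpointed and returned, not the
#' final-epoch weights. Fully reproducible when `config$seed` is set.
#'
#' @param x n x d matrix scaled to \[0, 1\] (one subtype's samples).
#' @param config an [ae_config()].
#' @return object of class `ae_fit`: list with `model` (the checkpointed
#'   `ae_model`), `history` (per-epoch train/validation loss and `best_epoch`)
#'   and `config`.
#' @export
ae_train <- function(x, config = ae_config()) {
  stopifnot(inherits(config, "ae_config"))
  if (!is.matrix(x)) stop("x must be a matrix (samples x genes)")
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples to train")
  if (config$h >= ncol(x)) stop("bottleneck h must be smaller than gene count")
  res <- with_seed_or_state(config$seed, .ae_train_cpp(
    x, config$h, config$lambda, config$batch_size, config$epochs,
    config$learning_rate, config$beta1, config$beta2, config$epsilon,
    config$lr_decay, config$decay_start, config$val_fraction,
    config$penalty == "l21", config$use_bias, isTRUE(config$nonneg_init),
    config$b1_init %||% 0, config$init_scale %||% 1,
    config$lambda_warmup %||% 0))
  model <- structure(c(res$model, list(gene_ids = colnames(x))),
                     class = "ae_model")
  structure(list(model = model,
                 history = list(train_loss = res$train_loss,
                                val_loss = res$val_loss,
                                best_epoch = res$best_epoch),
                 config = config),
            class = "ae_fit")
}

#' Feature scores from a trained model
#'
#' The score of gene i is the Euclidean norm of row i of the encoder weight
#' matrix W1: genes whose rows were driven to zero by the L2,1 penalty
#' contribute nothing to the bottleneck representation and score 0.
#'
#' @param model an `ae_model` or `ae_fit`.
#' @return named non-negative numeric vector of length d (names are gene ids
#'   when the model carries them).
#' @export
feature_scores <- function(model) {
  if (inherits(model, "ae_fit")) model <- model$model
  stopifnot(inherits(model, "ae_model"))
  s <- sqrt(rowSums(model$W1^2))
  if (!is.null(model$gene_ids)) names(s) <- model$gene_ids
  s
}

#' Select the top-k scoring genes
#'
#' Genes are ranked by descending score; ties are broken by ascending gene id
#' so the selection is deterministic.
#'
#' @param scores named numeric vector from [feature_scores()].
#' @param k number of genes to keep (default 3000).
#' @return data.frame of class `marker_set` with columns `rank`, `gene_id`,
#'   `score`.
#' @export
top_k_features <- function(scores, k = 3000L) {
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  if (k > length(scores))
    stop("k = ", k, " exceeds the number of genes (", length(scores), ")")
  ord <- order(-scores, names(scores))
  sel <- ord[seq_len(k)]
  structure(data.frame(rank = seq_len(k), gene_id = names(scores)[sel],
                       score = unname(scores[sel]),
                       stringsAsFactors = FALSE),
            class = c("marker_set", "data.frame"))
}

#' @export
print.ae_fit <- function(x, ...) {
  h <- x$history
  cat("Row-sparse autoencoder fit: d =", x$model$d, ", h =", x$model$h,
      "\n  lambda =", x$config$lambda, ", epochs =", x$config$epochs,
      "\n  best validation loss", format(min(h$val_loss), digits = 5),
      "at epoch", h$best_epoch, "\n")
  invisible(x)
}

#' Serialize / restore a trained model as plain JSON
#'
#' Portable text archive of the weight matrices, configuration and history;
#' round-trips exactly at double precision.
#'
#' @param fit an `ae_fit`.
#' @param path file path for the JSON archive.
#' @return `path` (for `ae_save`); an `ae_fit` (for `ae_load`).
#' @export
ae_save <- function(fit, path) {
  stopifnot(inherits(fit, "ae_fit"))
  obj <- list(
    W1 = fit$model$W1, W2 = fit$model$W2,
    b1 = fit$model$b1, b2 = fit$model$b2,
    d = fit$model$d, h = fit$model$h,
    gene_ids = fit$model$gene_ids, use_bias = fit$model$use_bias,
    config = unclass(fit$config), history = fit$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname ae_save
#' @export
ae_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(W1 = obj$W1, W2 = obj$W2, d = obj$d, h = obj$h,
                          gene_ids = obj$gene_ids,
                          use_bias = isTRUE(obj$use_bias)),
                     class = "ae_model")
  if (isTRUE(obj$use_bias)) { model$b1 <- obj$b1; model$b2 <- obj$b2 }
  cfg <- do.call(ae_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(model = model,
                 history = obj$history,
                 config = cfg),
            class = "ae_fit")
}

#' Training configuration tuned for small cohorts
#'
#' Convenience preset for matrices of tens of samples by hundreds of genes
#' (pilot studies, simulations): a narrow bottleneck, a stronger row-sparsity
#' weight warmed up over the first third of training, small-scale
#' initialisation (gradient dynamics then align to the leading variance
#' directions in order, which makes the selected gene set far more
#' reproducible across runs), full-batch Adam run long with a late step-size
#' anneal, biases with a positive hidden-bias start (all hidden ReLU units
#' begin active), and no internal validation split. See [ae_config()] for
#' the meaning of each field.
#'
#' @param h bottleneck width.
#' @param lambda row-sparsity weight.
#' @param epochs training epochs.
#' @param seed seed, or NULL to consume the current RNG stream.
#' @param ... further overrides passed to [ae_config()].
#' @return an `ae_config`.
#' @export
ae_config_small <- function(h = 16L, lambda = 0.1, epochs = 8000L,
                            seed = NULL, ...) {
  ae_config(h = h, lambda = lambda, epochs = epochs,
            learning_rate = 5e-3, lr_decay = 0.1^(1 / (0.3 * epochs)),
            decay_start = 0.7, batch_size = 64L, use_bias = TRUE,
            b1_init = 1, init_scale = 0.03, lambda_warmup = 0.3,
            val_fraction = 0, seed = seed, ...)
}
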