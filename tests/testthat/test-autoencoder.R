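test_that("weight initialisation is shaped, seeded and Glorot-bounded", {
  m <- ae_init(10, 3, seed = 1)
  expect_equal(dim(m$W1), c(10L, 3L))
  expect_equal(dim(m$W2), c(3L, 10L))
  lim <- sqrt(6 / 13)
  expect_true(all(abs(m$W1) <= lim))
  expect_identical(m, ae_init(10, 3, seed = 1))
  expect_false(identical(m$W1, ae_init(10, 3, seed = 2)$W1))
  expect_error(ae_init(5, 5, seed = 1), "h < d")
})

test_that("forward pass is ReLU(ReLU(XW1)W2) with no biases", {
  m <- ae_init(4, 2, seed = 3)
  expect_equal(ae_forward(matrix(0, 3, 4), m), matrix(0, 3, 4))
  # negative preactivation clamps the bottleneck to zero
  m2 <- structure(list(W1 = matrix(c(1, -5), 2, 1),
                       W2 = matrix(c(1, 1), 1, 2), d = 2L, h = 1L,
                       use_bias = FALSE), class = "ae_model")
  f <- ae_forward(matrix(c(1, 1), 1, 2), m2, detail = TRUE)
  expect_equal(f$z1[1, 1], -4)
  expect_equal(f$a1[1, 1], 0)
  expect_equal(f$xhat, matrix(0, 1, 2))
  # non-negative weights give elementwise non-negative output
  m3 <- m
  m3$W1 <- abs(m3$W1); m3$W2 <- abs(m3$W2)
  x <- matrix(runif(12), 3, 4)
  expect_true(all(ae_forward(x, m3) >= 0))
  expect_error(ae_forward(matrix(0, 2, 5), m), "columns")
})

test_that("the L2,1 norm sums row Euclidean norms", {
  expect_equal(l21_norm(diag(2)), 2)
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  w <- matrix(rnorm(12), 3, 4)
  expect_equal(l21_norm(3.5 * w), 3.5 * l21_norm(w))
  expect_equal(l21_norm(matrix(0, 4, 4)), 0)
})

test_that("objective matches its closed forms", {
  # zero model, lambda 0: sum of squares over 2n
  m <- structure(list(W1 = matrix(0, 3, 2), W2 = matrix(0, 2, 3),
                      d = 3L, h = 2L, use_bias = FALSE), class = "ae_model")
  x <- matrix(1:6 / 6, 2, 3)
  expect_equal(ae_objective(x, m, 0), sum(x^2) / 4)
  # perfect reconstruction at lambda 0 is exactly zero
  expect_equal(ae_objective(matrix(0, 2, 3), m, 0), 0)
  # penalty adds lambda * l21(W1)
  m$W1 <- rbind(c(3, 4), c(0, 0), c(0, 0))
  expect_equal(ae_objective(matrix(0, 2, 3), m, 0.1), 0.5)
  expect_error(ae_objective(x[0, , drop = FALSE], m, 0), "empty")
})

test_that("analytic gradients match central finite differences", {
  # random small instances kept away from ReLU kinks
  n_checked <- 0
  for (i in 1:8) {
    inst <- withr::with_seed(100 + i, {
      d <- sample(4:8, 1); h <- sample(1:3, 1); n <- sample(2:6, 1)
      model <- ae_init(d, h, seed = NULL)
      list(model = model, x = matrix(runif(n * d, 0.2, 1), n, d),
           lam = sample(c(0, 1e-3, 1e-2), 1))
    })
    f <- ae_forward(inst$x, inst$model, detail = TRUE)
    if (min(abs(f$z1)) < 1e-3 || min(abs(f$z2)) < 1e-3) next
    g <- ae_gradient(inst$x, inst$model, inst$lam)
    eps <- 1e-5
    for (p in c("W1", "W2")) {
      num <- inst$model[[p]]
      for (j in seq_along(num)) {
        up <- inst$model; up[[p]][j] <- up[[p]][j] + eps
        dn <- inst$model; dn[[p]][j] <- dn[[p]][j] - eps
        num[j] <- (ae_objective(inst$x, up, inst$lam) -
                     ae_objective(inst$x, dn, inst$lam)) / (2 * eps)
      }
      denom <- pmax(abs(num) + abs(g[[p]]), 1e-6)
      expect_lt(max(abs(num - g[[p]]) / denom), 1e-5)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 4)
})

test_that("training is reproducible and the checkpoint is the best epoch", {
  x <- withr::with_seed(1, matrix(runif(8 * 12), 8, 12,
    dimnames = list(paste0("s", 1:8), paste0("g", 1:12))))
  cfg <- ae_config(h = 3, lambda = 1e-4, epochs = 40, batch_size = 4,
                   learning_rate = 1e-2, seed = 7)
  f1 <- ae_train(x, cfg)
  f2 <- ae_train(x, cfg)
  expect_identical(f1$model$W1, f2$model$W1)
  expect_identical(f1$history, f2$history)
  h <- f1$history
  expect_length(h$train_loss, 40)
  expect_equal(h$best_epoch, which.min(h$val_loss))
  expect_lte(h$train_loss[h$best_epoch], h$train_loss[1])
})

test_that("a dominant penalty shrinks the encoder below initialisation", {
  x <- withr::with_seed(2, matrix(runif(6 * 10), 6, 10,
    dimnames = list(paste0("s", 1:6), paste0("g", 1:10))))
  init <- withr::with_seed(9, ae_init(10, 2, seed = NULL))
  cfg <- ae_config(h = 2, lambda = 1e3, epochs = 200, learning_rate = 1e-2,
                   val_fraction = 0, seed = 9)
  fit <- ae_train(x, cfg)
  expect_lt(l21_norm(fit$model$W1), l21_norm(init$W1))
})

test_that("an unpenalised wide model reconstructs a low-rank instance", {
  # exactly representable: non-negative rank-2 data, bottleneck 3 of 6
  x <- withr::with_seed(5, {
    c_mat <- matrix(runif(8 * 2, 0.2, 1), 8, 2)
    b_mat <- matrix(runif(2 * 6, 0.2, 1), 2, 6)
    out <- c_mat %*% b_mat
    dimnames(out) <- list(paste0("s", 1:8), paste0("g", 1:6))
    out / max(out)
  })
  # non-negative init: the exactly-representable solution has non-negative
  # weights, and all ReLUs start (and stay) in their active region
  cfg <- ae_config(h = 3, lambda = 0, epochs = 6000, learning_rate = 1e-2,
                   lr_decay = (1e-2)^(1 / 3000), decay_start = 0.5,
                   val_fraction = 0, seed = 11, nonneg_init = TRUE,
                   init_scale = 0.5)
  fit <- ae_train(x, cfg)
  expect_lt(min(fit$history$train_loss), fit$history$train_loss[1] / 10)
})

test_that("feature scores are encoder row norms", {
  m <- structure(list(W1 = rbind(c(3, 4), c(0, 0), c(1, 0)),
                      W2 = matrix(0, 2, 3), d = 3L, h = 2L,
                      use_bias = FALSE, gene_ids = c("gA", "gB", "gC")),
                 class = "ae_model")
  s <- feature_scores(m)
  expect_equal(s, c(gA = 5, gB = 0, gC = 1))
  # invariant to permuting bottleneck columns
  m2 <- m
  m2$W1 <- m$W1[, 2:1]
  expect_equal(feature_scores(m2), s)
})

test_that("top-k selection is score-ordered with lexicographic ties", {
  s <- c(gA = 5, gB = 1, gC = 3)
  tk <- top_k_features(s, 2)
  expect_equal(tk$gene_id, c("gA", "gC"))
  expect_equal(tk$score, c(5, 3))
  expect_equal(top_k_features(s, 3)$gene_id, c("gA", "gC", "gB"))
  tied <- c(gZ = 2, gA = 2, gM = 2)
  expect_equal(top_k_features(tied, 2)$gene_id, c("gA", "gM"))
  expect_error(top_k_features(s, 4), "exceeds")
})

test_that("the sparsity path is monotone in lambda on a fixed toy", {
  x <- simulate_expression(sim_config(
    n_per_class = c(A = 12L), d = 40L, m_per_class = 6L,
    n_outlier_genes = 0L, zero_prob = 0, seed = 21))$expr
  xs <- apply_minmax(x, fit_minmax(x))
  active <- sapply(c(0, 1e-6, 1e-4, 1e-2), function(lam) {
    cfg <- ae_config(h = 4, lambda = lam, epochs = 800,
                     learning_rate = 1e-2, lr_decay = (1e-1)^(1 / 800),
                     val_fraction = 0, seed = 13, use_bias = TRUE)
    s <- feature_scores(ae_train(xs, cfg))
    sum(s > 1e-6 * max(s))
  })
  expect_true(all(diff(active) <= 0))
})

test_that("models round-trip through the JSON archive", {
  x <- withr::with_seed(3, matrix(runif(6 * 9), 6, 9,
    dimnames = list(paste0("s", 1:6), paste0("g", 1:9))))
  fit <- ae_train(x, ae_config(h = 2, lambda = 1e-4, epochs = 15, seed = 4))
  tf <- withr::local_tempfile(fileext = ".json")
  ae_save(fit, tf)
  back <- ae_load(tf)
  expect_equal(back$model$W1, fit$model$W1)
  expect_equal(back$model$W2, fit$model$W2)
  expect_equal(back$history$val_loss, fit$history$val_loss)
  expect_equal(feature_scores(back), feature_scores(fit))
})
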