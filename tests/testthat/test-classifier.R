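test_that("class weights are n/(k*n_v)", {
  balanced <- class_weights(rep(c("A", "B", "C", "D"), each = 25))
  expect_equal(unname(balanced$weights), rep(1, 4))
  two <- class_weights(rep(c("A", "B"), c(6, 2)))
  expect_equal(unname(two$weights), c(2 / 3, 2))
  # imbalance of the order seen in receptor-labelled cohorts
  cohort <- class_weights(c(TNBC = 148, `HER2-enriched` = 55,
                            LuminalA = 589, LuminalB = 170))
  expect_equal(unname(cohort$weights["TNBC"]), 962 / 592)
  expect_equal(cohort$n, 962)
  expect_equal(cohort$k, 4)
  # exact identity sum_v w_v n_v = n
  counts <- c(A = 7, B = 13, C = 29)
  cw <- class_weights(counts)
  expect_equal(sum(cw$weights * counts), sum(counts))
  expect_error(class_weights(c(A = 5, B = 0)), "positive")
})

test_that("weighted Gini implements the literal weighted impurity", {
  expect_equal(weighted_gini(c(A = 4, B = 0)), 0)       # pure node, w = 1
  expect_equal(weighted_gini(c(A = 1, B = 1)), 0.5)
  expect_equal(weighted_gini(c(A = 3, B = 1), c(A = 2 / 3, B = 2)), 0.5)
  # with unit weights it reduces to 1 - sum p^2
  cnt <- c(A = 3, B = 5, C = 2)
  expect_equal(weighted_gini(cnt), 1 - sum((cnt / 10)^2))
  # invariant to scaling all counts
  w <- c(A = 1.5, B = 0.75, C = 0.9)
  expect_equal(weighted_gini(cnt, w), weighted_gini(7 * cnt, w))
  expect_error(weighted_gini(c(A = 0, B = 0)), "no samples")
})

test_that("unit class weights match an unweighted forest exactly", {
  toy <- imbalanced_toy(30, 30, sep = 2, seed = 8)
  cfg <- rf_config(n_trees = 50, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 5)
  w1 <- structure(list(weights = c(major = 1, minor = 1), n = 60, k = 2),
                  class = "class_weights")
  f_w <- fit_rf(toy$x, toy$y, config = cfg, weights = w1)
  f_u <- fit_rf(toy$x, toy$y, config = cfg, weights = NULL)
  expect_equal(predict(f_w, toy$x), predict(f_u, toy$x))
})

test_that("a separable toy is classified perfectly in training", {
  toy <- imbalanced_toy(40, 40, sep = 8, seed = 12)
  cfg <- rf_config(n_trees = 50, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 5)
  fit <- fit_rf(toy$x, toy$y, config = cfg)
  pr <- predict(fit, toy$x)
  expect_equal(colnames(pr)[max.col(pr)], as.character(toy$y))
})

test_that("class weighting raises minority recall on overlapping classes", {
  toy <- imbalanced_toy(190, 10, sep = 1.2, seed = 42)
  test <- imbalanced_toy(1900, 100, sep = 1.2, seed = 43)
  cfg <- rf_config(n_trees = 200, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 5)
  f_u <- fit_rf(toy$x, toy$y, config = cfg)
  f_w <- fit_rf(toy$x, toy$y, config = cfg, weights = class_weights(toy$y))
  rec <- function(fit) {
    pr <- predict(fit, test$x)
    pred <- colnames(pr)[max.col(pr)]
    mean(pred[test$y == "minor"] == "minor")
  }
  expect_gt(rec(f_w), rec(f_u))
})

test_that("missing marker genes are reported by id", {
  toy <- imbalanced_toy(20, 20, sep = 3, seed = 2)
  expect_error(fit_rf(toy$x, toy$y, markers = c("f1", "absent_gene"),
                      config = rf_config(n_trees = 10, grid = data.frame(
                        max_depth = 0L, mtry_rule = "sqrt", min_node = 1L),
                        seed = 1)),
               "absent_gene")
})

test_that("grid search picks a row of the grid deterministically", {
  toy <- imbalanced_toy(40, 40, sep = 1.5, seed = 31)
  cfg <- rf_config(n_trees = 30, cv_folds = 3, seed = 9,
                   grid = expand.grid(max_depth = c(2L, 0L),
                                      mtry_rule = "sqrt",
                                      min_node = c(1L, 5L),
                                      stringsAsFactors = FALSE))
  fit <- fit_rf(toy$x, toy$y, config = cfg)
  expect_equal(nrow(fit$best), 1L)
  expect_equal(nrow(fit$cv_table), 4L)
  fit2 <- fit_rf(toy$x, toy$y, config = cfg)
  expect_identical(fit$best, fit2$best)
  expect_equal(fit$cv_table$cv_accuracy, fit2$cv_table$cv_accuracy)
})

test_that("evaluation reports exact metrics for a perfect classifier", {
  toy <- imbalanced_toy(30, 15, sep = 10, seed = 3)
  cfg <- rf_config(n_trees = 50, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 5)
  fit <- fit_rf(toy$x, toy$y, config = cfg)
  rep <- evaluate_classifier(fit, toy$x, toy$y)
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$auc), c(1, 1))
  expect_equal(rep$weighted_auc, 1)
  expect_equal(rep$weighted_f1, 1)
  # confusion-trace identity
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion), rep$accuracy)
})

test_that("trapezoidal AUC equals the Mann-Whitney U formulation", {
  # oracle: P(score_pos > score_neg) + 0.5 P(equal), by enumeration
  auc_u <- function(pos, neg) {
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (seed in 1:5) {
    sc <- withr::with_seed(seed, round(runif(30), 2))  # ties included
    y <- withr::with_seed(100 + seed, rbinom(30, 1, 0.5))
    if (length(unique(y)) < 2) next
    r <- pROC::roc(response = y, predictor = sc, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    expect_equal(as.numeric(pROC::auc(r)), auc_u(sc[y == 1], sc[y == 0]))
  }
})

test_that("coin-flip scores give chance-level AUC", {
  y <- rep(c(0, 1), each = 400)
  sc <- withr::with_seed(77, runif(800))
  r <- pROC::roc(response = y, predictor = sc, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  expect_lt(abs(as.numeric(pROC::auc(r)) - 0.5), 0.05)
})

test_that("a class absent from the test set is excluded with a warning", {
  # three well-separated classes; class C never appears in the test set
  xy <- withr::with_seed(14, {
    x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2),
               matrix(rnorm(20, 12), ncol = 2))
    colnames(x) <- c("f1", "f2")
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    list(x = x, y = factor(rep(c("A", "B", "C"), c(30, 30, 10))))
  })
  cfg <- rf_config(n_trees = 30, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 5)
  fit <- fit_rf(xy$x, xy$y, config = cfg)
  keep <- xy$y != "C"
  expect_warning(rep <- evaluate_classifier(fit, xy$x[keep, ], xy$y[keep]),
                 "C")
  expect_true(is.na(rep$auc["C"]))
  expect_false(is.na(rep$auc["A"]))
  expect_false(is.na(rep$weighted_auc))
})

test_that("the bundled weighted-Gini forest fits and predicts sanely", {
  toy <- imbalanced_toy(25, 25, sep = 6, seed = 21)
  f <- gini_forest(toy$x, toy$y, n_trees = 25, seed = 3,
                   weights = c(major = 1, minor = 1))
  pr <- predict_gini_forest(f, toy$x)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), ignore_attr = TRUE)
  expect_equal(colnames(pr)[max.col(pr)], as.character(toy$y))
  # reachable through fit_rf as the eq6 engine
  cfg <- rf_config(n_trees = 25, grid = data.frame(
    max_depth = 0L, mtry_rule = "sqrt", min_node = 1L), seed = 3)
  fit <- fit_rf(toy$x, toy$y, config = cfg, impurity = "eq6")
  pr2 <- predict(fit, toy$x)
  expect_equal(colnames(pr2)[max.col(pr2)], as.character(toy$y))
})
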