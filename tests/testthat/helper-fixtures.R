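# small deterministic fixtures shared across test files

toy_expr <- function(values, n_samples = nrow(values)) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

# matrix whose gene columns have prescribed zero fractions over 100 samples
zero_fraction_matrix <- function(fracs) {
  n <- 100L
  m <- sapply(fracs, function(f) {
    v <- rep(1, n)
    v[seq_len(round(f * n))] <- 0
    v
  })
  toy_expr(m)
}

# two well-separated gaussian classes in 2-d, imbalanced
imbalanced_toy <- function(n_major = 190L, n_minor = 10L, sep = 1.2,
                           seed = 42L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_major * 2, 0), ncol = 2),
               matrix(rnorm(n_minor * 2, sep), ncol = 2))
    colnames(x) <- c("f1", "f2")
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    list(x = x, y = factor(rep(c("major", "minor"), c(n_major, n_minor))))
  })
}

# two disjoint triangles: a graph MCL must split into its components
two_triangle_graph <- function() {
  e <- data.frame(protein1 = c("a", "b", "c", "x", "y", "z"),
                  protein2 = c("b", "c", "a", "y", "z", "x"),
                  score = 0.9)
  build_graph(e, markers = c("a", "b", "c", "x", "y", "z"))
}

# two K5 cliques joined by one bridge edge: granularity toy for inflation
two_clique_graph <- function(bridge_weight = 0.75) {
  cl <- function(v) t(utils::combn(v, 2))
  e1 <- cl(paste0("a", 1:5)); e2 <- cl(paste0("b", 1:5))
  e <- data.frame(protein1 = c(e1[, 1], e2[, 1], "a1"),
                  protein2 = c(e1[, 2], e2[, 2], "b1"),
                  score = c(rep(0.9, nrow(e1) + nrow(e2)), bridge_weight))
  build_graph(e, markers = c(paste0("a", 1:5), paste0("b", 1:5)))
}
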