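#' Read a STRING-style edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score` (detached-format
#' compatible; extra columns ignored). Scores on the raw 0-1000 integer scale
#' are auto-rescaled to \[0, 1\] by /1000; scores already in \[0, 1\] are kept.
#'
#' @param path file path.
#' @return data.frame with columns `protein1`, `protein2`, `score`.
#' @export
read_string_edges <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(dt) <- tolower(names(dt))
  need <- c("protein1", "protein2")
  sc <- intersect(c("combined_score", "score"), names(dt))
  if (!all(need %in% names(dt)) || length(sc) == 0)
    stop("edge table needs columns protein1, protein2, combined_score")
  s <- dt[[sc[1]]]
  bad <- which(!is.finite(s) | s < 0)
  if (length(bad) > 0)
    stop("malformed edge score at data row ", bad[1])
  if (any(s > 1)) s <- s / 1000
  if (any(s > 1)) stop("edge scores exceed 1 even after 0-1000 rescaling")
  data.frame(protein1 = as.character(dt$protein1),
             protein2 = as.character(dt$protein2),
             score = s, stringsAsFactors = FALSE)
}

#' Build a confidence-filtered interaction graph over a marker set
#'
#' Induces the subgraph on the marker genes, keeps only edges with
#' confidence strictly greater than `min_conf` (0.7 by default, so a score of
#' exactly 0.7 is dropped), removes self-loops, and collapses duplicate edges
#' keeping the maximum score.
#'
#' @param edges data.frame from [read_string_edges()] (columns `protein1`,
#'   `protein2`, `score` in \[0, 1\]).
#' @param markers character vector of marker gene ids (or a `marker_set`).
#' @param min_conf confidence threshold (strict).
#' @return an undirected [igraph::graph] with edge attribute `weight`; nodes
#'   are the marker genes present in at least one retained edge plus all
#'   markers (isolated markers stay as degree-0 nodes).
#' @export
build_graph <- function(edges, markers, min_conf = 0.7) {
  if (is.data.frame(markers)) markers <- markers$gene_id
  markers <- unique(as.character(markers))
  stopifnot(all(c("protein1", "protein2", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1))
    stop("edge scores must lie in [0, 1]; rescale 0-1000 scores first")
  keep <- edges$protein1 %in% markers & edges$protein2 %in% markers &
    edges$score > min_conf & edges$protein1 != edges$protein2
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) > 0) {
    a <- pmin(e$protein1, e$protein2)
    b <- pmax(e$protein1, e$protein2)
    key <- paste(a, b, sep = "\r")
    agg <- tapply(e$score, key, max)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    e <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    weight = as.numeric(agg), stringsAsFactors = FALSE)
  } else {
    e <- data.frame(from = character(0), to = character(0),
                    weight = numeric(0))
  }
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = sort(markers)))
}

#' Markov clustering (MCL) of an interaction graph
#'
#' Adds self-loops of weight 1 (standard MCL practice, aiding convergence),
#' column-normalises the adjacency matrix to a column-stochastic flow matrix,
#' then alternates expansion (matrix squaring) and inflation (elementwise
#' power `inflation` followed by column renormalisation), pruning entries
#' below `prune`, until the maximum absolute column change drops below `tol`
#' or `max_iter` is reached (a warning is raised on non-convergence and the
#' current partition returned). Clusters are read off the attractor
#' structure of the converged matrix: each node joins the cluster of the
#' attractor holding the largest mass in its column, ties to the lowest id;
#' attractor rows linked through shared nodes merge.
#'
#' @param graph undirected igraph with optional `weight` edge attribute.
#' @param inflation inflation exponent (granularity knob; 2.5 by default).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the flow matrix.
#' @param prune entries below this are zeroed each iteration.
#' @return object of class `module_partition`: list with `clusters` (list of
#'   character vectors, largest first; ties by lowest member id),
#'   `membership` (named integer vector), `n_iter`, `converged`,
#'   `colsum_dev` (per-iteration max deviation of column sums from 1) and
#'   `inflation`.
#' @export
mcl_cluster <- function(graph, inflation = 2.5, max_iter = 100L,
                        tol = 1e-6, prune = 1e-5) {
  stopifnot(igraph::is_igraph(graph))
  nv <- igraph::vcount(graph)
  if (nv == 0) stop("graph has no nodes")
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(nv))
  a <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
    igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
  a <- (a + t(a)) / 2                      # enforce symmetry
  diag(a) <- 1                             # self-loops
  m <- sweep(a, 2, colSums(a), `/`)
  converged <- FALSE
  it <- 0L
  colsum_dev <- numeric(0)
  while (it < max_iter) {
    it <- it + 1L
    m_new <- m %*% m                       # expansion
    m_new <- m_new^inflation               # inflation
    m_new[m_new < prune] <- 0
    cs <- colSums(m_new)
    zero_col <- cs == 0
    if (any(zero_col)) {                   # fully pruned column: keep self
      m_new[cbind(which(zero_col), which(zero_col))] <- 1
      cs[zero_col] <- 1
    }
    m_new <- sweep(m_new, 2, cs, `/`)
    colsum_dev <- c(colsum_dev, max(abs(colSums(m_new) - 1)))
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; returning the current partition")
  # attractor of node j = row with the largest mass in column j (ties: lowest)
  attr_of <- apply(m, 2, which.max)
  comp <- igraph::components(igraph::graph_from_edgelist(
    cbind(seq_len(nv), attr_of), directed = FALSE))$membership
  membership <- setNames(as.integer(comp), ids)
  clusters <- split(ids, membership)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) min(cl), ""))
  clusters <- unname(lapply(clusters[ord], sort))
  remap <- setNames(seq_along(ord), names(split(ids, membership))[ord])
  membership <- remap[as.character(membership)]
  names(membership) <- ids
  structure(list(clusters = clusters, membership = membership,
                 n_iter = it, converged = converged,
                 colsum_dev = colsum_dev, inflation = inflation),
            class = "module_partition")
}

#' Summarise a module partition
#'
#' @param partition a `module_partition`.
#' @param min_size modules strictly larger than this are counted as reported
#'   modules (the > 2-gene convention by default).
#' @return list with `n_modules` (above the size cutoff), `n_clusters`,
#'   `largest`, `size_histogram`.
#' @export
module_summary <- function(partition, min_size = 2L) {
  sz <- lengths(partition$clusters)
  list(n_modules = sum(sz > min_size), n_clusters = length(sz),
       largest = if (length(sz)) max(sz) else 0L,
       size_histogram = table(sz))
}

#' @export
print.module_partition <- function(x, ...) {
  s <- module_summary(x)
  cat("MCL partition (inflation ", x$inflation, "): ", s$n_clusters,
      " clusters, ", s$n_modules, " modules with > 2 genes, largest = ",
      s$largest, "\n", sep = "")
  invisible(x)
}
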