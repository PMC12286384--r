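#' Consensus (replicate-and-intersect) configuration
#'
#' The stability-selection protocol trains the autoencoder `runs_per_seed`
#' times under each of `n_seeds` seed blocks, takes the intersection of the
#' per-run top-k gene sets within each block, and finally intersects across
#' blocks. The reference protocol on real cohorts uses 30 runs x 16 seeds
#' with k = 3000.
#'
#' @param runs_per_seed training runs per seed block.
#' @param n_seeds number of independent seed blocks.
#' @param seeds explicit integer seeds (length `n_seeds`); when NULL they are
#'   derived deterministically from `master_seed` (distinct draws from
#'   `sample.int(.Machine$integer.max %/% 2, n_seeds)` under that seed).
#' @param master_seed master seed used to generate `seeds` when unset.
#' @param k per-run selection size.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(runs_per_seed = 30L, n_seeds = 16L, seeds = NULL,
                             master_seed = 1L, k = 3000L) {
  stopifnot(runs_per_seed >= 1, n_seeds >= 1, k >= 1)
  if (is.null(seeds)) {
    seeds <- withr::with_seed(as.integer(master_seed),
                              sample.int(.Machine$integer.max %/% 2L,
                                         n_seeds))
  }
  if (length(seeds) != n_seeds || anyDuplicated(seeds))
    stop("seeds must be ", n_seeds, " distinct integers")
  structure(list(runs_per_seed = as.integer(runs_per_seed),
                 n_seeds = as.integer(n_seeds), seeds = as.integer(seeds),
                 k = as.integer(k)),
            class = "consensus_config")
}

#' Run replicate trainings under one seed block
#'
#' Seeds the generator once with `seed`, then executes `n_runs` sequential
#' train/score/select cycles without reseeding in between, so runs differ
#' through the advancing generator state (weight initialisation, internal
#' validation split and batch order all draw from it).
#'
#' @param x scaled class matrix (samples x genes).
#' @param train_config an [ae_config()]; its own `seed` is ignored here.
#' @param n_runs number of replicate runs.
#' @param k top-k size per run.
#' @param seed seed for the block.
#' @return list of `n_runs` `marker_set` data.frames (each of k genes).
#' @export
run_replicates <- function(x, train_config, n_runs = 30L, k = 3000L,
                           seed = 1L) {
  train_config$seed <- NULL
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_runs), function(r) {
      fit <- tryCatch(ae_train(x, train_config), error = function(e) {
        stop("replicate run ", r, " failed: ", conditionMessage(e))
      })
      top_k_features(feature_scores(fit), k)
    })
  })
}

#' Intersect gene-id sets
#'
#' @param sets list of character vectors (or `marker_set` data.frames).
#' @return character vector, the exact intersection, sorted ascending.
#' @export
intersect_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  ids <- lapply(sets, function(s) if (is.data.frame(s)) s$gene_id else s)
  sort(Reduce(intersect, ids))
}

#' Consensus marker set across runs and seeds
#'
#' For each seed block, intersects its per-run top-k sets; then intersects
#' the per-block consensus sets across all blocks. The surviving genes are
#' ordered by their mean score across every contributing run, descending.
#' An empty final intersection is returned (with a warning), not an error.
#'
#' @param x scaled class matrix (samples x genes).
#' @param train_config an [ae_config()].
#' @param config a [consensus_config()].
#' @return `marker_set` data.frame with columns `rank`, `gene_id`, `score`
#'   (mean score across runs) and `n_runs_present`, plus attributes
#'   `per_seed_sizes` (the per-block funnel) and `seeds`.
#' @export
consensus_markers <- function(x, train_config, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  per_seed <- vector("list", config$n_seeds)
  score_sum <- setNames(numeric(ncol(x)), colnames(x))
  score_n <- setNames(integer(ncol(x)), colnames(x))
  for (b in seq_len(config$n_seeds)) {
    runs <- run_replicates(x, train_config, config$runs_per_seed,
                           config$k, config$seeds[b])
    for (r in runs) {
      score_sum[r$gene_id] <- score_sum[r$gene_id] + r$score
      score_n[r$gene_id] <- score_n[r$gene_id] + 1L
    }
    per_seed[[b]] <- intersect_sets(runs)
  }
  final <- intersect_sets(per_seed)
  if (length(final) == 0)
    warning("consensus across seeds is empty; consider a larger k or ",
            "fewer/looser replicates")
  mean_score <- ifelse(score_n[final] > 0, score_sum[final] / score_n[final], 0)
  ord <- order(-mean_score, final)
  out <- data.frame(rank = seq_along(final), gene_id = final[ord],
                    score = unname(mean_score[ord]),
                    n_runs_present = unname(score_n[final][ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("marker_set", "data.frame"),
            per_seed_sizes = lengths(per_seed), seeds = config$seeds)
}

#' Write a marker set as TSV
#'
#' @param markers a `marker_set` data.frame.
#' @param path output path.
#' @export
write_marker_set <- function(markers, path) {
  data.table::fwrite(as.data.frame(markers), path, sep = "\t")
  invisible(path)
}
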