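#' Configuration for the synthetic multi-subtype expression generator
#'
#' Emulates an FPKM-like cohort: non-negative, heavy-tailed (log-normal)
#' expression, zero inflation, imbalanced classes, a handful of
#' inflated-mean outlier genes, and per-class planted markers. A marker gene
#' in its own class is bimodally dysregulated across tumours: per sample it
#' receives a log-shift of `effect_size * z`, where z is 3 (strongly up,
#' probability 1/2) or -1 (down, probability 1/2), independently per marker
#' gene. The mean log-shift in class is therefore exactly `effect_size`,
#' while the on/off split makes markers high-variance within their class --
#' the property the row-sparse autoencoder detects after per-gene min-max
#' scaling (a pure constant shift would be removed by the scaler). With
#' `effect_size = 0` markers follow exactly the base distribution.
#'
#' @param n_per_class named integer vector of class sizes (default
#'   emulates a 4-subtype imbalance: 30/15/60/25).
#' @param d total number of genes.
#' @param m_per_class planted markers per class.
#' @param effect_size mean log-shift of a marker in its class (>= 0).
#' @param effect_tier_range half-width of the deterministic per-marker tier:
#'   marker effects within a class are graded multiplicatively from
#'   `1 + effect_tier_range` down to `1 - effect_tier_range` (mean exactly
#'   1), reflecting that real marker panels mix strong and moderate markers.
#' @param base_meanlog,base_meanlog_sd per-gene baseline log-mean drawn
#'   N(base_meanlog, base_meanlog_sd).
#' @param base_sdlog within-gene log-sd.
#' @param zero_prob zero-inflation probability; scalar or length-d vector.
#' @param n_outlier_genes genes given an inflated mean (log-shift
#'   `outlier_shift`) to exercise outlier removal.
#' @param outlier_shift log-shift of the outlier genes.
#' @param shared_markers if TRUE, class marker blocks overlap by half with
#'   the next class's block (emulating shared programs); default FALSE
#'   (class-exclusive markers).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(TNBC = 30L, `HER2-enriched` = 15L,
                                       LuminalA = 60L, LuminalB = 25L),
                       d = 500L, m_per_class = 50L, effect_size = 1.0,
                       effect_tier_range = 0.2,
                       base_meanlog = 1.4, base_meanlog_sd = 0.4,
                       base_sdlog = 0.15, zero_prob = 0.02,
                       n_outlier_genes = 10L, outlier_shift = 5.0,
                       shared_markers = FALSE, seed = 11L) {
  stopifnot(effect_size >= 0, all(zero_prob >= 0), all(zero_prob <= 1),
            n_outlier_genes >= 0, all(n_per_class >= 1))
  k <- length(n_per_class)
  if (k * m_per_class + n_outlier_genes > d)
    stop("infeasible config: markers (", k * m_per_class, ") + outliers (",
         n_outlier_genes, ") exceed d = ", d)
  stopifnot(effect_tier_range >= 0, effect_tier_range < 1)
  structure(list(n_per_class = n_per_class, d = as.integer(d),
                 m_per_class = as.integer(m_per_class),
                 effect_size = effect_size,
                 effect_tier_range = effect_tier_range,
                 base_meanlog = base_meanlog,
                 base_meanlog_sd = base_meanlog_sd, base_sdlog = base_sdlog,
                 zero_prob = zero_prob,
                 n_outlier_genes = as.integer(n_outlier_genes),
                 outlier_shift = outlier_shift,
                 shared_markers = shared_markers, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-subtype expression cohort with planted markers
#'
#' See [sim_config()] for the generative model. Gene ids are `g0001`, ...;
#' sample ids carry their class. Marker blocks occupy the first genes, the
#' outlier genes the last ones, with identities recorded in the returned
#' truth object.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (samples x genes matrix), `labels` (named factor
#'   of subtypes) and `truth` (list: `markers` per class, `outlier_genes`,
#'   `config`).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    k <- length(config$n_per_class)
    classes <- names(config$n_per_class)
    if (is.null(classes)) classes <- paste0("class", seq_len(k))
    n <- sum(config$n_per_class)
    d <- config$d
    gene_ids <- sprintf("g%04d", seq_len(d))
    labels <- factor(rep(classes, config$n_per_class), levels = classes)
    sample_ids <- paste0(rep(classes, config$n_per_class), "_s",
                         unlist(lapply(config$n_per_class, seq_len)))
    # planted marker blocks (first k*m genes), outliers at the tail
    markers <- list()
    step <- if (config$shared_markers) ceiling(config$m_per_class / 2)
            else config$m_per_class
    for (ci in seq_len(k)) {
      start <- (ci - 1L) * step + 1L
      markers[[classes[ci]]] <- gene_ids[start:(start + config$m_per_class - 1L)]
    }
    outliers <- if (config$n_outlier_genes > 0)
      gene_ids[(d - config$n_outlier_genes + 1L):d] else character(0)
    meanlog <- rnorm(d, config$base_meanlog, config$base_meanlog_sd)
    names(meanlog) <- gene_ids
    meanlog[outliers] <- meanlog[outliers] + config$outlier_shift
    logx <- matrix(rnorm(n * d, 0, config$base_sdlog), n, d,
                   dimnames = list(sample_ids, gene_ids))
    logx <- sweep(logx, 2, meanlog, `+`)
    if (config$effect_size > 0) {
      for (ci in seq_len(k)) {
        rows <- which(labels == classes[ci])
        mk <- markers[[classes[ci]]]
        # per-gene bimodal dysregulation: up (3) or down (-1), mean shift 1
        z <- matrix(ifelse(rbinom(length(rows) * length(mk), 1, 0.5) == 1,
                           3, -1),
                    length(rows), length(mk))
        tier <- seq(1 + config$effect_tier_range,
                    1 - config$effect_tier_range, length.out = length(mk))
        logx[rows, mk] <- logx[rows, mk, drop = FALSE] +
          config$effect_size * sweep(z, 2, tier, `*`)
      }
    }
    x <- exp(logx)
    zp <- rep_len(config$zero_prob, d)
    mask <- matrix(runif(n * d), n, d) < rep(zp, each = n)
    x[mask] <- 0
    names(labels) <- sample_ids
    list(expr = x,
         labels = labels,
         truth = list(markers = markers, outlier_genes = outliers,
                      config = config))
  })
}

#' Receptor-status metadata consistent with subtype labels
#'
#' Convenience inverse of [assign_subtype()] for synthetic cohorts: emits a
#' canonical ER/PR/HER2 pattern per subtype (TNBC all-negative;
#' HER2-enriched ER-/PR-/HER2+; luminal A ER+/PR+/HER2-; luminal B
#' ER+/PR+/HER2+).
#'
#' @param labels named vector/factor of subtype labels.
#' @return data.frame with columns `sample_id`, `er`, `pr`, `her2`.
#' @export
receptor_from_subtype <- function(labels) {
  map <- list(TNBC = c("negative", "negative", "negative"),
              `HER2-enriched` = c("negative", "negative", "positive"),
              LuminalA = c("positive", "positive", "negative"),
              LuminalB = c("positive", "positive", "positive"))
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), names(map))
  if (length(bad) > 0) stop("no receptor pattern for: ",
                            paste(bad, collapse = ", "))
  m <- do.call(rbind, map[lab])
  data.frame(sample_id = if (!is.null(names(labels))) names(labels)
             else as.character(seq_along(labels)),
             er = m[, 1], pr = m[, 2], her2 = m[, 3],
             stringsAsFactors = FALSE)
}

#' Random toy interaction edges for module-detection tests
#'
#' Generates a weighted random graph over the given genes from a planted
#' block structure: within-block edges appear with probability `p_in` and
#' high confidence, between-block edges with probability `p_out` and lower
#' confidence. Synthetic stand-in for a STRING-style edge list.
#'
#' @param genes character vector of node ids.
#' @param n_blocks number of planted blocks.
#' @param p_in,p_out within/between-block edge probabilities.
#' @param conf_in,conf_out mean confidence of within/between edges.
#' @param seed integer seed.
#' @return data.frame with columns `protein1`, `protein2`, `score` and an
#'   attribute `blocks` (the planted membership).
#' @export
simulate_edges <- function(genes, n_blocks = 3L, p_in = 0.6, p_out = 0.02,
                           conf_in = 0.9, conf_out = 0.4, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    block <- rep_len(seq_len(n_blocks), length(genes))
    pairs <- utils::combn(seq_along(genes), 2)
    same <- block[pairs[1, ]] == block[pairs[2, ]]
    prob <- ifelse(same, p_in, p_out)
    keep <- runif(ncol(pairs)) < prob
    conf <- pmin(1, pmax(0, rnorm(ncol(pairs),
                                  ifelse(same, conf_in, conf_out), 0.05)))
    out <- data.frame(protein1 = genes[pairs[1, keep]],
                      protein2 = genes[pairs[2, keep]],
                      score = conf[keep], stringsAsFactors = FALSE)
    attr(out, "blocks") <- setNames(block, genes)
    out
  })
}
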