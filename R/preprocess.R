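#' Assign a breast-cancer subtype from hormone-receptor status
#'
#' Maps ER/PR/HER2 receptor status to one of the four clinical subtypes:
#' ER-/PR-/HER2- is triple-negative (TNBC); ER-/HER2+ is HER2-enriched
#' (PR status is not consulted); ER+/PR+/HER2- is luminal A; ER+ with HER2+
#' is luminal B, as is ER+/PR-/HER2- (luminal A requires PR+ explicitly).
#' Any pattern involving an unknown, or not matching a rule, is "unassigned".
#'
#' @param er,pr,her2 character vectors with values "positive", "negative" or
#'   "unknown" (recycled to a common length); see [normalize_receptor()]-style
#'   inputs via [read_metadata()].
#' @param overrides optional data.frame with columns `er`, `pr`, `her2`,
#'   `subtype` consulted before the built-in rules (exact level match).
#' @return character vector of subtype labels or "unassigned".
#' @examples
#' assign_subtype("negative", "negative", "negative")  # TNBC
#' assign_subtype("positive", "positive", "negative")  # LuminalA
#' @export
assign_subtype <- function(er, pr, her2, overrides = NULL) {
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(as.character(er), n)
  pr <- rep_len(as.character(pr), n)
  her2 <- rep_len(as.character(her2), n)
  lv <- c("positive", "negative", "unknown")
  if (!all(c(er, pr, her2) %in% lv))
    stop("receptor status must be one of: ", paste(lv, collapse = ", "))
  out <- rep("unassigned", n)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- er == overrides$er[i] & pr == overrides$pr[i] &
        her2 == overrides$her2[i]
      out[hit] <- overrides$subtype[i]
    }
  }
  free <- out == "unassigned"
  out[free & er == "negative" & pr == "negative" & her2 == "negative"] <- "TNBC"
  free <- out == "unassigned"
  out[free & er == "negative" & her2 == "positive"] <- "HER2-enriched"
  free <- out == "unassigned"
  out[free & er == "positive" & pr == "positive" & her2 == "negative"] <- "LuminalA"
  free <- out == "unassigned"
  out[free & er == "positive" & her2 == "positive"] <- "LuminalB"
  free <- out == "unassigned"
  out[free & er == "positive" & pr == "negative" & her2 == "negative"] <- "LuminalB"
  out
}

#' Drop genes that are zero in too many samples
#'
#' Removes genes whose fraction of zero values across samples is strictly
#' greater than `max_zero_fraction` ("more than 75%" by default); a gene
#' sitting exactly on the threshold is kept. Gene order is preserved.
#'
#' @param x samples x genes expression matrix.
#' @param max_zero_fraction keep genes with zero fraction `<=` this value.
#' @return the filtered matrix.
#' @export
filter_zero_genes <- function(x, max_zero_fraction = 0.75) {
  validate_expr(x)
  zf <- colMeans(x == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep))
    stop("no gene has zero fraction <= ", max_zero_fraction,
         "; all genes removed by the zero filter")
  x[, keep, drop = FALSE]
}

#' Remove outlier genes by the distribution of per-gene means
#'
#' Computes each gene's mean expression across samples, then the mean and
#' population standard deviation of that vector of gene means, and removes
#' genes whose mean lies strictly more than `n_sd` standard deviations from
#' the centre. With a degenerate spread (sd = 0) nothing is removed and a
#' warning is raised.
#'
#' @param x samples x genes matrix with at least 2 genes.
#' @param n_sd width of the retained band in standard deviations.
#' @return the filtered matrix.
#' @export
remove_outlier_genes <- function(x, n_sd = 1.0) {
  validate_expr(x)
  if (ncol(x) < 2) stop("need at least 2 genes to assess outliers")
  gm <- colMeans(x)
  mu <- mean(gm)
  sigma <- sqrt(mean((gm - mu)^2))  # population SD
  if (sigma == 0) {
    warning("gene means have zero spread; no outlier genes removed")
    return(x)
  }
  keep <- abs(gm - mu) <= n_sd * sigma
  x[, keep, drop = FALSE]
}

#' Fit per-gene min-max scaling parameters
#'
#' @param x samples x genes matrix (the fitting set).
#' @return object of class `minmax_params` holding per-gene min and max.
#' @export
fit_minmax <- function(x) {
  validate_expr(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 gene_ids = colnames(x)),
            class = "minmax_params")
}

#' Apply min-max scaling
#'
#' Per-gene transform (x - min) / (max - min) with the parameters learned by
#' [fit_minmax()]. Constant genes (max = min) map to 0. Values from data other
#' than the fitting set may fall outside \[0, 1\] and are not clipped.
#'
#' @param x samples x genes matrix; gene ids must match `params` exactly.
#' @param params a `minmax_params` object.
#' @return scaled matrix of the same shape.
#' @export
apply_minmax <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!identical(colnames(x), params$gene_ids))
    stop("gene ids of the matrix do not match the scaling parameters")
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, `-`)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], `/`)
  out[, !nz] <- 0
  out
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets preserving class proportions:
#' each class contributes floor(train_fraction * n_v) training samples, and
#' the remaining training slots (to reach round(train_fraction * n) overall)
#' go to the classes with the largest fractional remainders (ties broken by
#' class-name order). Reproducible under `seed`.
#'
#' @param labels factor or character vector of class labels, named by sample
#'   id (or names taken from `sample_ids`).
#' @param train_fraction fraction of samples assigned to training.
#' @param seed integer seed (isolated; the global RNG stream is untouched).
#' @param sample_ids optional ids if `labels` is unnamed.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L,
                             sample_ids = names(labels)) {
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(labels))
  labels <- as.character(labels)
  stopifnot(length(sample_ids) == length(labels))
  if (anyNA(labels)) stop("every sample must be labeled")
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("classes with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  n <- length(labels)
  base <- floor(train_fraction * cnt)
  rem <- train_fraction * cnt - base
  extra <- round(train_fraction * n) - sum(base)
  take <- setNames(as.integer(base), names(cnt))
  if (extra > 0) {
    ord <- names(cnt)[order(-rem, names(cnt))]
    bump <- head(ord, extra)
    take[bump] <- take[bump] + 1L
  }
  train <- with_seed_or_state(seed, {
    unlist(lapply(names(cnt), function(cl) {
      ids <- sample_ids[labels == cl]
      sample(ids, take[[cl]])
    }), use.names = FALSE)
  })
  test <- setdiff(sample_ids, train)
  if (length(test) == 0) stop("empty test set: train_fraction too high")
  if (length(train) == 0) stop("empty training set: train_fraction too low")
  list(train = sort(train), test = sort(test))
}

#' Preprocess an expression matrix into per-subtype scaled matrices
#'
#' Runs the fixed preprocessing order — subtype assignment, zero filter,
#' outlier-gene removal — then splits the matrix by subtype and min-max
#' scales each subtype matrix per gene to \[0, 1\].
#'
#' @param x samples x genes matrix.
#' @param meta metadata data.frame from [read_metadata()] (receptor columns or
#'   a subtype column).
#' @param max_zero_fraction,n_sd filter parameters; see [filter_zero_genes()]
#'   and [remove_outlier_genes()].
#' @return list with `matrices` (named list of scaled per-subtype matrices),
#'   `scaling` (per-subtype `minmax_params`), `labels` (named subtype vector
#'   over assigned samples) and `report` (gene/sample counts at each stage).
#' @export
preprocess_subtypes <- function(x, meta, max_zero_fraction = 0.75,
                                n_sd = 1.0) {
  validate_expr(x)
  if ("subtype" %in% names(meta)) {
    lab <- setNames(as.character(meta$subtype), meta$sample_id)
  } else {
    lab <- setNames(assign_subtype(meta$er, meta$pr, meta$her2),
                    meta$sample_id)
  }
  lab <- lab[intersect(rownames(x), names(lab))]
  assigned <- lab[lab %in% subtype_levels()]
  if (length(assigned) == 0) stop("no sample received a subtype label")
  x <- x[names(assigned), , drop = FALSE]
  report <- list(n_samples_input = nrow(x), n_genes_input = ncol(x),
                 class_counts = as.list(table(assigned)))
  x <- filter_zero_genes(x, max_zero_fraction)
  report$n_genes_after_zero_filter <- ncol(x)
  x <- remove_outlier_genes(x, n_sd)
  report$n_genes_after_outlier_filter <- ncol(x)
  mats <- list()
  scaling <- list()
  for (cl in intersect(subtype_levels(), unique(assigned))) {
    xc <- x[names(assigned)[assigned == cl], , drop = FALSE]
    p <- fit_minmax(xc)
    mats[[cl]] <- apply_minmax(xc, p)
    scaling[[cl]] <- p
  }
  list(matrices = mats, scaling = scaling, labels = assigned, report = report)
}
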