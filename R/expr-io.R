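#' @importFrom data.table fread fwrite
#' @importFrom stats predict quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

#' Validate an expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix of
#' non-negative values with samples in rows and genes in columns; row names
#' are unique sample identifiers and column names unique gene identifiers.
#'
#' @param x numeric matrix, samples x genes.
#' @return `x`, invisibly, after validation.
#' @export
validate_expr <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (samples x genes)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs sample row names and gene column names")
  if (anyDuplicated(rownames(x))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(x))) stop("duplicated gene ids")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite expression values")
  if (any(x < 0)) stop("negative expression values; FPKM-like input expected")
  invisible(x)
}

#' Read a delimited expression table
#'
#' Expects a TSV/CSV with gene identifiers in the first column and sample
#' identifiers in the header (the common genes-by-samples layout); set
#' `orientation = "samples_by_genes"` when rows are samples. Gzip-compressed
#' files are accepted. The returned matrix is always samples x genes.
#'
#' @param path file path.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @return numeric matrix, samples x genes.
#' @export
read_expression <- function(path,
                            orientation = c("genes_by_samples",
                                            "samples_by_genes")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  validate_expr(m)
  m
}

#' Write an expression matrix as genes-by-samples TSV
#'
#' @param x samples x genes matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  validate_expr(x)
  g <- t(x)
  out <- data.frame(gene_id = rownames(g), g, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# canonical receptor levels from free-text markings
normalize_receptor <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("positive", "pos", "+", "1", "true")] <- "positive"
  out[x %in% c("negative", "neg", "-", "−", "0", "false")] <- "negative"
  out
}

#' Read a sample-metadata table
#'
#' Accepts either a receptor-status table with columns `sample_id`, `er`,
#' `pr`, `her2` (values such as Positive/Negative/pos/neg/+/- in any case;
#' anything else becomes "unknown") or a precomputed label table with columns
#' `sample_id`, `subtype`.
#'
#' @param path TSV/CSV path.
#' @return data.frame with `sample_id` plus either normalised receptor columns
#'   or a `subtype` column.
#' @export
read_metadata <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(dt) <- tolower(names(dt))
  if (!"sample_id" %in% names(dt)) stop("metadata needs a sample_id column")
  dt$sample_id <- as.character(dt$sample_id)
  if ("subtype" %in% names(dt)) {
    dt[, c("sample_id", "subtype")]
  } else if (all(c("er", "pr", "her2") %in% names(dt))) {
    data.frame(sample_id = dt$sample_id,
               er = normalize_receptor(dt$er),
               pr = normalize_receptor(dt$pr),
               her2 = normalize_receptor(dt$her2),
               stringsAsFactors = FALSE)
  } else {
    stop("metadata needs either er/pr/her2 columns or a subtype column")
  }
}

#' Read a marker table (one gene id per row)
#'
#' @param path TSV with a `gene_id` column (other columns ignored).
#' @return character vector of gene ids.
#' @export
read_marker_file <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(dt) <- tolower(names(dt))
  if (!"gene_id" %in% names(dt)) stop("marker file needs a gene_id column")
  unique(as.character(dt$gene_id))
}

# run code with an isolated, seeded RNG when seed is given; otherwise use
# (and advance) the current generator state -- the behaviour replicate
# protocols rely on
with_seed_or_state <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

subtype_levels <- function() c("TNBC", "HER2-enriched", "LuminalA", "LuminalB")

`%||%` <- function(a, b) if (is.null(a)) b else a
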