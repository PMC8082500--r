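#' Expression set: a gene-by-sample matrix with sample metadata
#'
#' `expression_set()` bundles a non-negative gene x sample expression matrix
#' (normalized units such as FPKM) with a per-sample metadata table. It is the
#' universal input of the pipeline; every downstream function takes it first.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Must be non-negative with no missing
#'   values: the pipeline's correlation machinery assumes complete data, so
#'   missingness is rejected at construction rather than imputed.
#' @param metadata Data frame with columns `sample_id`, `condition`, `tissue`,
#'   `replicate`; exactly one row per sample in `values`.
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (matrix) and `metadata` (tibble, ordered as the matrix columns).
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' md <- data.frame(sample_id = c("s1", "s2", "s3"), condition = "A",
#'                  tissue = c("lung", "lung", "liver"), replicate = c(1, 2, 1))
#' es <- expression_set(m, md)
#' es
expression_set <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate gene id: '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("duplicate sample id: '", dup, "'", call. = FALSE)
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", rownames(values)[idx[1]], "', sample '",
         colnames(values)[idx[2]], "'; missing values are rejected at load",
         call. = FALSE)
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", rownames(values)[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'", call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  needed <- c("sample_id", "condition", "tissue", "replicate")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    dup <- metadata$sample_id[duplicated(metadata$sample_id)][1]
    stop("duplicate metadata row for sample '", dup, "'", call. = FALSE)
  }
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent)) {
    stop("sample '", absent[1], "' present in matrix but absent from metadata",
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ]
  structure(list(values = values, metadata = metadata), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("<expr_set> ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  cat("  conditions: ", paste(unique(x$metadata$condition), collapse = ", "),
      "\n  tissues:    ", paste(unique(x$metadata$tissue), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Gene and sample accessors for an expression set
#' @param x An `expr_set`.
#' @return Character vectors of gene or sample identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression set by gene and/or sample
#' @param x An `expr_set`.
#' @param i Gene ids or indices (rows); missing keeps all.
#' @param j Sample ids or indices (columns); missing keeps all.
#' @param ... Unused.
#' @return An `expr_set`.
#' @export
`[.expr_set` <- function(x, i, j, ...) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  expression_set(v, x$metadata[x$metadata$sample_id %in% colnames(v), ])
}

#' Long (tidy) view of an expression set
#'
#' @param x An `expr_set`.
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) holding the expression
#'   value and the sample's metadata.
#' @export
as_tibble.expr_set <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.vector(x$values)
  )
  dplyr::left_join(long, x$metadata, by = "sample_id")
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file is tab-separated with a header of sample ids and a
#' first column named `gene_id`; the metadata file carries the columns
#' `sample_id`, `condition`, `tissue`, `replicate`. Validation is strict:
#' duplicated identifiers, non-numeric cells, negative values and samples
#' without metadata are rejected with a located error.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @return An `expr_set`.
#' @export
read_expression <- function(expr_path, meta_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(
                            gene_id = readr::col_character(),
                            .default = readr::col_character()))
  if (!"gene_id" %in% names(expr)) {
    stop("expression file must have a first column named 'gene_id'",
         call. = FALSE)
  }
  genes <- expr$gene_id
  vals <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (length(genes) == 1L) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell '", vals[bad[1, 1], bad[1, 2]], "' at gene '",
         genes[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'",
         call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  expression_set(num, meta)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression()]: values written with full precision so a
#' write/read round trip is value-identical.
#'
#' @param x An `expr_set`.
#' @param expr_path,meta_path Output paths.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, expr_path, meta_path) {
  tab <- tibble::as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(tab, expr_path)
  readr::write_tsv(x$metadata, meta_path)
  invisible(x)
}

#' Filter genes by median absolute deviation (MAD)
#'
#' Lowly and invariantly expressed genes are indistinguishable from sampling
#' noise, so the pipeline keeps only the most variable fraction of genes:
#' genes are ranked by the MAD of their expression, `median(|x - median(x)|)`,
#' computed over all samples pooled across conditions, and the top
#' `ceiling(keep_fraction * n)` are retained. Ties are broken stably by gene
#' id (lexicographic), so the result is deterministic.
#'
#' @param x An `expr_set`.
#' @param keep_fraction Fraction of genes to keep, in (0, 1]. Default 0.5
#'   (the top half), the pipeline's operating point.
#' @param log2 If `TRUE`, compute MAD on `log2(x + 1)`-transformed values
#'   (the filter's ranking only; returned values stay on the input scale).
#' @return The filtered `expr_set`, with a `filter_report` attribute (see
#'   [filter_report()]) recording per-gene MAD values and the kept set.
#' @export
#' @examples
#' es <- simulate_expression(sim_config(seed = 1))$expr
#' dim(mad_filter(es, 0.5))
mad_filter <- function(x, keep_fraction = 0.5, log2 = FALSE) {
  stopifnot(inherits(x, "expr_set"))
  if (!(keep_fraction > 0 && keep_fraction <= 1)) {
    stop("`keep_fraction` must be in (0, 1]", call. = FALSE)
  }
  v <- x$values
  if (log2) v <- log2(v + 1)
  mads <- apply(v, 1, function(row) stats::median(abs(row - stats::median(row))))
  n <- nrow(v)
  n_kept <- as.integer(ceiling(keep_fraction * n))
  if (length(unique(mads)) == 1L && keep_fraction < 1) {
    warning("all genes have identical MAD; ranking is ties-only ",
            "(stable lexicographic by gene id)", call. = FALSE)
  }
  ord <- order(-mads, rownames(v), method = "radix")
  kept_genes <- rownames(v)[ord][seq_len(n_kept)]
  report <- list(
    n_input_genes = n,
    n_kept = n_kept,
    keep_fraction = keep_fraction,
    mad = tibble::tibble(
      gene_id = rownames(v)[ord],
      mad = mads[ord],
      kept = rownames(v)[ord] %in% kept_genes
    )
  )
  out <- expression_set(x$values[rownames(x$values) %in% kept_genes, ,
                                 drop = FALSE],
                        x$metadata)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report attached by [mad_filter()]
#' @param x A filtered `expr_set`.
#' @return A list with `n_input_genes`, `n_kept`, `keep_fraction` and a
#'   per-gene tibble `mad` (gene_id, mad, kept), ranked as filtered.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Hierarchical sample clustering with outlier flagging
#'
#' Quality control before network construction: samples are clustered by
#' average-linkage hierarchical clustering on the Euclidean distance between
#' their expression vectors, and a sample is flagged as an outlier when the
#' height at which it first merges into the tree is an extreme z-score
#' relative to the other samples' first-merge heights.
#'
#' @param x An `expr_set` with at least 3 samples.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param z_cutoff Z-score above which a sample's first-merge height flags it
#'   as an outlier. Default 2.5.
#' @return An object of class `sample_clustering`: list with the `hclust`
#'   tree and a tibble `samples` (sample_id, merge_height, z, is_outlier).
#' @export
cluster_samples <- function(x, linkage = "average", z_cutoff = 2.5) {
  stopifnot(inherits(x, "expr_set"))
  if (ncol(x$values) < 3) stop("need at least 3 samples", call. = FALSE)
  d <- stats::dist(t(x$values))
  hc <- stats::hclust(d, method = linkage)
  n <- ncol(x$values)
  first_merge <- vapply(seq_len(n), function(s) {
    hc$height[which(apply(hc$merge == -s, 1, any))[1]]
  }, numeric(1))
  sd_h <- stats::sd(first_merge)
  z <- if (is.na(sd_h) || sd_h == 0) rep(0, n) else
    (first_merge - mean(first_merge)) / sd_h
  structure(list(
    hclust = hc,
    samples = tibble::tibble(
      sample_id = colnames(x$values),
      merge_height = first_merge,
      z = z,
      is_outlier = z > z_cutoff
    )
  ), class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", nrow(x$samples), " samples, ",
      sum(x$samples$is_outlier), " outlier(s)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sample_clustering <- function(x, ...) x$samples
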