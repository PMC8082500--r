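#' Round half away from zero
#'
#' Base R rounds half to even; replication percentages are conventionally
#' reported with half-up rounding (9/11 -> 81.82%).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Pairwise correlation tests among a candidate gene set
#'
#' Pearson correlation with a two-sided p-value from the Student t
#' statistic `t = r sqrt(n - 2) / sqrt(1 - r^2)` with n - 2 degrees of
#' freedom, for every unordered pair of the listed genes, over the selected
#' samples. Zero-variance genes are excluded with a warning.
#'
#' @param x An `expr_set` (e.g. a replication dataset).
#' @param genes Gene ids to test (default: all genes in `x`).
#' @param condition,tissue Optional sample restrictions (e.g. lung samples
#'   only).
#' @return Tibble (gene_a, gene_b, r, p, n) with gene_a < gene_b.
#' @export
pairwise_correlation <- function(x, genes = NULL, condition = NULL,
                                 tissue = NULL) {
  stopifnot(inherits(x, "expr_set"))
  md <- x$metadata
  keep <- rep(TRUE, nrow(md))
  if (!is.null(condition)) keep <- keep & md$condition == condition
  if (!is.null(tissue)) keep <- keep & md$tissue == tissue
  if (sum(keep) < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(genes)) genes <- rownames(x$values)
  miss <- setdiff(genes, rownames(x$values))
  genes <- intersect(genes, rownames(x$values))
  v <- x$values[genes, keep, drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded", call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("need at least 2 testable genes", call. = FALSE)
  cc <- stats::cor(t(v))
  n <- ncol(v)
  pair <- which(upper.tri(cc), arr.ind = TRUE)
  g1 <- rownames(cc)[pair[, 1]]
  g2 <- rownames(cc)[pair[, 2]]
  r <- cc[pair]
  out <- tibble::tibble(gene_a = pmin(g1, g2), gene_b = pmax(g1, g2),
                        r = r, p = cor_pvalue(r, n), n = n)
  attr(out, "missing_genes") <- miss
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Call replicated co-expression edges
#'
#' A candidate edge is confirmed when the pair is significantly positively
#' correlated in the replication data (`p < alpha` with positive r). Pairs with
#' a gene absent from the replication dataset are marked `untestable` and
#' later excluded from the replication-rate denominator, mirroring the
#' treatment of genes without probe annotation.
#'
#' @param candidates Tibble/data frame with columns `gene_a`, `gene_b`.
#' @param tests Tibble from [pairwise_correlation()] on the replication
#'   dataset.
#' @param alpha Significance level (default 0.05).
#' @param require_positive Require r > 0 (default `TRUE`).
#' @return Tibble (gene_a, gene_b, r, p, verdict) with verdict in
#'   confirmed/not_confirmed/untestable.
#' @export
replicate_edges <- function(candidates, tests, alpha = 0.05,
                            require_positive = TRUE) {
  cand <- tibble::tibble(gene_a = pmin(candidates$gene_a, candidates$gene_b),
                         gene_b = pmax(candidates$gene_a, candidates$gene_b))
  m <- match(paste(cand$gene_a, cand$gene_b),
             paste(tests$gene_a, tests$gene_b))
  r <- tests$r[m]
  p <- tests$p[m]
  verdict <- dplyr::case_when(
    is.na(m) ~ "untestable",
    p < alpha & (!require_positive | r > 0) ~ "confirmed",
    TRUE ~ "not_confirmed"
  )
  tibble::tibble(gene_a = cand$gene_a, gene_b = cand$gene_b, r = r, p = p,
                 verdict = verdict)
}

#' Replication-rate summary
#'
#' The rate is `100 * n_confirmed / n_candidate` (untestable pairs excluded
#' from the denominator), rounded half-up to two decimals — 9 of 11 gives
#' 81.82.
#'
#' @param verdicts Tibble from [replicate_edges()], or a character vector
#'   of verdicts.
#' @return One-row tibble (n_candidate, n_confirmed, n_untestable, rate).
#' @export
replication_rate <- function(verdicts) {
  v <- if (is.data.frame(verdicts)) verdicts$verdict else verdicts
  n_unt <- sum(v == "untestable")
  n_cand <- sum(v != "untestable")
  n_conf <- sum(v == "confirmed")
  rate <- if (n_cand == 0) NA_real_ else
    round_half_up(100 * n_conf / n_cand, 2)
  if (n_cand == 0) warning("no testable candidate edges", call. = FALSE)
  tibble::tibble(n_candidate = n_cand, n_confirmed = n_conf,
                 n_untestable = n_unt, rate = rate)
}

#' Overlap count between two gene sets
#'
#' Case-normalized intersection size (identifiers are assumed pre-mapped to
#' a shared namespace; case differences between datasets are tolerated).
#'
#' @param genes_a,genes_b Character vectors.
#' @return Integer overlap count.
#' @export
module_overlap <- function(genes_a, genes_b) {
  length(intersect(unique(toupper(genes_a)), unique(toupper(genes_b))))
}
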