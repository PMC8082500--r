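#' Unsigned weighted adjacency from expression
#'
#' The co-expression network follows the weighted-network protocol: the
#' adjacency between genes i and j is `|cor(x_i, x_j)|^beta` (unsigned,
#' Pearson), so soft thresholding with power `beta` suppresses weak
#' correlations without a hard cutoff. The diagonal is stored as 1 but is
#' excluded from every connectivity and topology-concept sum downstream.
#'
#' @param x An `expr_set`, or a numeric genes x samples matrix.
#' @param beta Soft-thresholding power, integer >= 1.
#' @return A symmetric gene x gene matrix with entries in \[0, 1\] and a
#'   `beta` attribute. Zero-variance genes get adjacency 0 to every other
#'   gene (with a warning).
#' @export
adjacency_matrix <- function(x, beta = 6) {
  v <- if (inherits(x, "expr_set")) x$values else x
  stopifnot(is.matrix(v), is.numeric(v))
  if (beta < 1) stop("`beta` must be >= 1", call. = FALSE)
  if (ncol(v) < 3) stop("need at least 3 samples", call. = FALSE)
  cc <- suppressWarnings(stats::cor(t(v)))
  if (anyNA(cc)) {
    warning("zero-variance gene(s); their correlations set to 0",
            call. = FALSE)
    cc[is.na(cc)] <- 0
  }
  a <- abs(cc)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit of a connectivity sequence
#'
#' Bins the connectivities into `n_bins` equal-width bins and regresses
#' `log10(mean frequency)` on `log10(mean k)` over the non-empty bins. The
#' returned index is the regression R-squared signed by the negated slope,
#' so only a *decreasing* log-log relationship (the scale-free signature)
#' scores positively.
#'
#' @param k Numeric vector of whole-network connectivities (>= 0).
#' @param n_bins Number of equal-width bins (default 10).
#' @return Signed R-squared in \[-1, 1\]; 0 when fewer than 2 usable bins.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2) return(0)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & mean_k > 0 & freq > 0
  if (sum(ok) < 2) return(0)
  lx <- log10(mean_k[ok])
  ly <- log10(freq[ok])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["lx"]]
  sign(-slope) * r2
}

#' Choose the soft-thresholding power for approximate scale-free topology
#'
#' Evaluates a grid of powers and, for each, the signed scale-free fit index
#' of the whole-network connectivity distribution together with the mean
#' connectivity. The selected power is the smallest one reaching the fit
#' goal, or the best-fitting power when none does.
#'
#' @param x An `expr_set` or genes x samples matrix.
#' @param powers Integer grid of candidate powers (default 1:20).
#' @param r2_goal Scale-free fit goal (default 0.85, the pipeline's
#'   operating point).
#' @param n_bins Bins for [scale_free_fit()].
#' @return An object of class `soft_threshold`: list with `report`
#'   (tibble: beta, r_squared, mean_k), the selected `beta`, and `r2_goal`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_goal = 0.85,
                                n_bins = 10) {
  v <- if (inherits(x, "expr_set")) x$values else x
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[is.na(cc)] <- 0
  acc <- abs(cc)
  diag(acc) <- 0
  report <- purrr::map_dfr(powers, function(b) {
    a <- acc^b
    k <- rowSums(a)
    tibble::tibble(beta = b,
                   r_squared = scale_free_fit(k, n_bins),
                   mean_k = mean(k))
  })
  hit <- which(report$r_squared >= r2_goal)
  beta <- if (length(hit)) report$beta[hit[1]] else
    report$beta[which.max(report$r_squared)]
  structure(list(report = report, beta = beta, r2_goal = r2_goal),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("<soft_threshold> selected beta = ", x$beta, " (goal R² >= ",
      x$r2_goal, ")\n", sep = "")
  print(x$report, n = 5)
  invisible(x)
}

#' @export
tidy.soft_threshold <- function(x, ...) x$report

#' @export
glance.soft_threshold <- function(x, ...) {
  tibble::tibble(beta = x$beta, r2_goal = x$r2_goal,
                 r_squared = x$report$r_squared[x$report$beta == x$beta],
                 mean_k = x$report$mean_k[x$report$beta == x$beta])
}

#' Topological overlap similarity
#'
#' Converts an adjacency matrix into the (unsigned) topological overlap
#' matrix `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours `u != i, j`, measuring
#' how much two genes share neighbourhoods rather than merely correlate.
#' `1 - w` is the dissimilarity used for module detection.
#'
#' @param a Adjacency matrix from [adjacency_matrix()].
#' @return Symmetric matrix with entries in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  w <- (l + a0) / (kmin + 1 - a0)
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Detect co-expression modules by clustering on topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a static branch cut at a fixed fraction of the dendrogram
#' height range. Branches smaller than `min_size` fall back to the reserved
#' label `"unassigned"`; surviving modules are labelled `M1, M2, ...` in
#' decreasing size order. The static cut is a deliberate simplification of
#' dynamic branch cutting; at this pipeline's scale the recovered modules
#' are the same.
#'
#' @param tom TOM matrix from [tom_similarity()] (or any similarity with
#'   unit diagonal).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Cut position as a fraction of the dendrogram height
#'   range (default 0.95; high enough to keep genuine branches together,
#'   low enough that background genes joining near the top of the tree
#'   stay unassigned).
#' @return A tibble (gene_id, module) with the `hclust` tree in attribute
#'   `dendrogram`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.95) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  # average linkage is monotone; guard against float jitter on tied merges
  hc$height <- cummax(hc$height)
  hmin <- min(hc$height)
  hmax <- max(hc$height)
  h <- hmin + cut_height * (hmax - hmin)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- rep("unassigned", length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) {
      lab[raw == as.integer(keep[i])] <- paste0("M", i)
    }
  }
  out <- tibble::tibble(gene_id = rownames(tom), module = lab)
  attr(out, "dendrogram") <- hc
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression submatrix across samples: one representative
#' profile per module. The per-sample score vector has unit norm and its sign
#' is aligned so it correlates non-negatively with the module's mean
#' standardized expression.
#'
#' @param x An `expr_set`.
#' @param modules Tibble (gene_id, module) as from [detect_modules()];
#'   `"unassigned"` genes are skipped.
#' @return Object of class `module_eigengenes`: list with `values` (samples
#'   x modules matrix) and `var_explained` (named vector).
#' @export
module_eigengenes <- function(x, modules) {
  stopifnot(inherits(x, "expr_set"))
  mods <- setdiff(unique(modules$module), "unassigned")
  mods <- mods[order(mods)]
  if (!length(mods)) stop("no assigned modules", call. = FALSE)
  scores <- matrix(NA_real_, ncol(x$values), length(mods),
                   dimnames = list(colnames(x$values), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- modules$gene_id[modules$module == m]
    sub <- x$values[genes, , drop = FALSE]
    std <- t(scale(t(sub)))
    std[is.na(std)] <- 0  # zero-variance genes carry no signal
    sv <- svd(std, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::sd(colMeans(std)) > 0 &&
        stats::cor(e, colMeans(std)) < 0) e <- -e
    scores[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = scores, var_explained = ve),
            class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat("<module_eigengenes> ", ncol(x$values), " modules x ",
      nrow(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.module_eigengenes <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    module = rep(colnames(x$values), each = nrow(x$values)),
    eigengene = as.vector(x$values)
  )
}

#' Merge modules whose eigengenes are highly correlated
#'
#' Iteratively merges the module pair with the highest eigengene Pearson
#' correlation above `threshold` (recomputing eigengenes after each merge)
#' until no pair qualifies. The merged module keeps the label of the larger
#' partner (ties: lexicographically smaller label), and labels are finally
#' renumbered by size. Termination is guaranteed: each merge strictly
#' decreases the module count.
#'
#' @param x An `expr_set`.
#' @param modules Tibble (gene_id, module).
#' @param threshold Eigengene correlation above which modules merge
#'   (default 0.9).
#' @return Updated tibble (gene_id, module).
#' @export
merge_close_modules <- function(x, modules, threshold = 0.9) {
  stopifnot(inherits(x, "expr_set"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  modules <- tibble::as_tibble(modules)
  repeat {
    mods <- setdiff(unique(modules$module), "unassigned")
    if (length(mods) < 2) break
    me <- module_eigengenes(x, modules)
    cc <- stats::cor(me$values)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= threshold) break
    pair <- sort(colnames(cc)[best])
    sizes <- table(modules$module)[pair]
    winner <- if (sizes[1] >= sizes[2]) pair[1] else pair[2]
    loser <- setdiff(pair, winner)
    modules$module[modules$module == loser] <- winner
  }
  # renumber by decreasing size for a stable public labelling
  mods <- setdiff(unique(modules$module), "unassigned")
  if (length(mods)) {
    sizes <- table(modules$module)[mods]
    mods <- mods[order(-sizes, mods)]
    map <- stats::setNames(paste0("M", seq_along(mods)), mods)
    modules$module <- ifelse(modules$module == "unassigned", "unassigned",
                             unname(map[modules$module]))
  }
  modules
}

#' Gene significance for a tissue
#'
#' GS is the correlation between a gene's expression and the binary
#' indicator of the focal tissue, taken over one condition's samples
#' (or all samples). Reported as an absolute value by default, matching the
#' GS >= 0.8 conventions downstream; `signed = TRUE` keeps the sign.
#'
#' @param x An `expr_set`.
#' @param tissue Focal tissue (must appear in the metadata).
#' @param condition Restrict to one condition's samples; `NULL` = all.
#' @param signed Keep the correlation sign? Default `FALSE`.
#' @return Tibble (gene_id, gs). Zero-variance genes get GS = 0.
#' @export
gene_significance <- function(x, tissue, condition = NULL, signed = FALSE) {
  stopifnot(inherits(x, "expr_set"))
  md <- x$metadata
  keep <- if (is.null(condition)) rep(TRUE, nrow(md)) else
    md$condition == condition
  if (!tissue %in% md$tissue[keep]) {
    stop("tissue '", tissue, "' not present in the selected samples",
         call. = FALSE)
  }
  v <- x$values[, keep, drop = FALSE]
  ind <- as.numeric(md$tissue[keep] == tissue)
  gs <- suppressWarnings(as.vector(stats::cor(t(v), ind)))
  gs[is.na(gs)] <- 0
  tibble::tibble(gene_id = rownames(v), gs = if (signed) gs else abs(gs))
}

#' Per-gene module statistics: MM, kWithin, kTotal and per-tissue GS
#'
#' Module membership (MM) is the absolute correlation between a gene's
#' expression and its module's eigengene; kTotal is the gene's whole-network
#' connectivity (sum of adjacencies, diagonal excluded) and kWithin its
#' connectivity restricted to genes of the same module. GS columns
#' (`gs_<tissue>`) are added for every tissue via [gene_significance()].
#'
#' @param x An `expr_set`.
#' @param modules Tibble (gene_id, module).
#' @param a Adjacency matrix over the same genes.
#' @param condition Condition used for the GS columns; `NULL` = all samples.
#' @return Tibble (gene_id, module, mm, k_within, k_total, gs_*).
#' @export
module_stats <- function(x, modules, a, condition = NULL) {
  stopifnot(inherits(x, "expr_set"))
  genes <- modules$gene_id
  stopifnot(all(genes %in% rownames(a)), all(genes %in% rownames(x$values)))
  a <- a[genes, genes]
  a0 <- a
  diag(a0) <- 0
  k_total <- rowSums(a0)
  mod_of <- stats::setNames(modules$module, modules$gene_id)
  same <- outer(mod_of[genes], mod_of[genes], "==")
  k_within <- rowSums(a0 * same)
  me <- module_eigengenes(x, modules)
  mm <- vapply(genes, function(g) {
    m <- mod_of[[g]]
    if (!m %in% colnames(me$values)) return(NA_real_)
    v <- x$values[g, ]
    if (stats::sd(v) == 0) return(0)
    abs(stats::cor(v, me$values[, m]))
  }, numeric(1))
  out <- tibble::tibble(gene_id = genes, module = unname(mod_of[genes]),
                        mm = unname(mm), k_within = unname(k_within),
                        k_total = unname(k_total))
  md <- x$metadata
  tissues <- unique(if (is.null(condition)) md$tissue else
    md$tissue[md$condition == condition])
  for (t in tissues) {
    gs <- gene_significance(x, t, condition = condition)
    out[[paste0("gs_", t)]] <- gs$gs[match(out$gene_id, gs$gene_id)]
  }
  out
}

#' Fundamental network topology concepts of a (module) network
#'
#' With connectivities `k_i = sum_{j != i} a_ij` on the weighted adjacency
#' restricted to one module (diagonal excluded): density is the mean
#' off-diagonal adjacency; the cluster coefficient of node i is
#' `sum_{j,u} a_ij a_ju a_ui / ((sum_j a_ij)^2 - sum_j a_ij^2)` and MCC its
#' mean; centralization is `n/(n-2) * (max_i k_i/(n-1) - density)`; and
#' heterogeneity is the coefficient of variation of k (population variance).
#'
#' @param a Adjacency matrix (module submatrix), n >= 3.
#' @return One-row tibble (n, density, mcc, centralization, heterogeneity) —
#'   the DS/MCC/CL/HG summary reported per key module.
#' @export
network_concepts <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes (centralization undefined)",
                  call. = FALSE)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  density <- sum(a0) / (n * (n - 1))
  num <- diag(a0 %*% a0 %*% a0)
  den <- k^2 - rowSums(a0^2)
  cc <- ifelse(den > 0, num / den, 0)
  mcc <- mean(cc)
  centralization <- n / (n - 2) * (max(k) / (n - 1) - density)
  kv <- mean(k^2) - mean(k)^2  # population variance
  heterogeneity <- if (mean(k) > 0) sqrt(kv) / mean(k) else 0
  tibble::tibble(n = n, density = density, mcc = mcc,
                 centralization = centralization,
                 heterogeneity = heterogeneity)
}

#' Two-sided p-value of a Pearson correlation (Student t, n - 2 df)
#' @param r Correlation estimate(s).
#' @param n Sample size(s).
#' @return P-value(s) in (0, 1].
#' @export
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, df = n - 2)
}

#' Call key modules per tissue
#'
#' A module is key for a tissue when (1) the p-value of the correlation
#' between its eigengene and the tissue indicator beats the Bonferroni
#' threshold `alpha / (n_modules * n_tissues)` and (2) the median GS of the
#' module's genes for that tissue exceeds `gs_threshold`. With 21 modules
#' and 6 tissues the Bonferroni threshold at alpha = 0.05 is 3.97e-4.
#'
#' @param me A `module_eigengenes` object.
#' @param x The `expr_set` the eigengenes came from (for sample metadata).
#' @param stats Per-gene stats from [module_stats()] (for the `gs_*`
#'   columns).
#' @param alpha Family-wise error target (default 0.05).
#' @param gs_threshold Median-GS requirement (default 0.8).
#' @param condition Condition restriction for the eigengene-tissue
#'   correlation; `NULL` = all samples.
#' @return Tibble (module, tissue, r, p, bonferroni, median_gs, is_key).
#' @export
key_modules <- function(me, x, stats, alpha = 0.05, gs_threshold = 0.8,
                        condition = NULL) {
  stopifnot(inherits(me, "module_eigengenes"), inherits(x, "expr_set"))
  md <- x$metadata
  keep <- if (is.null(condition)) rep(TRUE, nrow(md)) else
    md$condition == condition
  samples <- md$sample_id[keep]
  ev <- me$values[samples, , drop = FALSE]
  tissues <- sort(unique(md$tissue[keep]))
  mods <- colnames(ev)
  m_tests <- length(mods) * length(tissues)
  bonf <- alpha / m_tests
  grid <- tidyr::expand_grid(module = mods, tissue = tissues)
  res <- purrr::pmap_dfr(grid, function(module, tissue) {
    ind <- as.numeric(md$tissue[keep] == tissue)
    r <- stats::cor(ev[, module], ind)
    p <- cor_pvalue(r, length(ind))
    gcol <- paste0("gs_", tissue)
    gvals <- stats[[gcol]][stats$module == module]
    med <- if (length(gvals)) stats::median(gvals) else NA_real_
    tibble::tibble(module = module, tissue = tissue, r = r, p = p,
                   bonferroni = bonf, median_gs = med,
                   is_key = p < bonf & !is.na(med) & med > gs_threshold)
  })
  res
}

#' Call hub genes within each module
#'
#' A hub gene satisfies, within its module: GS >= `gs_min` for the focal
#' tissue, module membership >= `mm_min`, and intramodular connectivity
#' (kWithin) ranked in the top `k_top` fraction of the module
#' (rank <= `ceiling(k_top * module size)`; ties broken by kWithin then gene
#' id). All three thresholds are inclusive.
#'
#' @param stats Tibble from [module_stats()].
#' @param tissue Either a single tissue name applied to every module, or a
#'   tibble (module, tissue) giving each module's focal tissue; modules
#'   without a focal tissue are skipped.
#' @param gs_min,mm_min,k_top The three hub thresholds (defaults 0.8, 0.95,
#'   0.2).
#' @return Tibble (gene_id, module, tissue, gs, mm, k_within, k_rank,
#'   is_hub).
#' @export
hub_genes <- function(stats, tissue, gs_min = 0.8, mm_min = 0.95,
                      k_top = 0.2) {
  mods <- setdiff(unique(stats$module), "unassigned")
  focal <- if (is.data.frame(tissue)) tibble::as_tibble(tissue) else
    tibble::tibble(module = mods, tissue = tissue)
  purrr::pmap_dfr(focal, function(module, tissue) {
    sub <- stats[stats$module == module, ]
    if (!nrow(sub)) return(NULL)
    gcol <- paste0("gs_", tissue)
    if (!gcol %in% names(sub)) {
      stop("no GS column for tissue '", tissue, "'", call. = FALSE)
    }
    ord <- order(-sub$k_within, sub$gene_id, method = "radix")
    rank <- integer(nrow(sub))
    rank[ord] <- seq_len(nrow(sub))
    cut <- ceiling(k_top * nrow(sub))
    tibble::tibble(
      gene_id = sub$gene_id, module = module, tissue = tissue,
      gs = sub[[gcol]], mm = sub$mm, k_within = sub$k_within,
      k_rank = rank,
      is_hub = sub[[gcol]] >= gs_min & sub$mm >= mm_min & rank <= cut
    )
  })
}
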