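#' Per-tissue mean expression profile
#'
#' Averages replicates within each tissue for one condition, producing the
#' gene x tissue profile that the tissue-specificity index and the
#' expression-pattern clustering operate on.
#'
#' @param x An `expr_set`.
#' @param condition Condition whose samples are averaged; `NULL` uses all
#'   samples (pooling conditions).
#' @return A tibble with `gene_id` and one numeric column per tissue.
#' @export
tissue_means <- function(x, condition = NULL) {
  stopifnot(inherits(x, "expr_set"))
  md <- x$metadata
  keep <- if (is.null(condition)) rep(TRUE, nrow(md)) else
    md$condition == condition
  if (!any(keep)) stop("no samples for condition '", condition, "'",
                       call. = FALSE)
  v <- x$values[, keep, drop = FALSE]
  tis <- md$tissue[keep]
  out <- tibble::tibble(gene_id = rownames(v))
  for (t in sort(unique(tis))) {
    out[[t]] <- unname(rowMeans(v[, tis == t, drop = FALSE]))
  }
  out
}

#' Tissue-specificity index (tau)
#'
#' For a profile of per-tissue means `x_1..x_N`,
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)`: 0 for a uniform (housekeeping)
#' profile, 1 for strictly single-tissue expression. Genes with `tau`
#' strictly above `ts_threshold` are flagged tissue-specific (TS). Tau is
#' invariant to positive rescaling of a profile and requires non-negative
#' values with a positive maximum; all-zero genes are excluded with a
#' warning (see attribute `excluded`).
#'
#' @param profile Tibble from [tissue_means()] (`gene_id` + >= 2 tissue
#'   columns).
#' @param ts_threshold TS call threshold (default 0.9, strict inequality).
#' @return Tibble (gene_id, tau, is_ts), with excluded gene ids in the
#'   `excluded` attribute.
#' @export
#' @examples
#' p <- tibble::tibble(gene_id = "g", a = 2, b = 4, c = 8)
#' tsi(p)$tau  # ((1 - 0.25) + (1 - 0.5) + 0) / 2 = 0.625
tsi <- function(profile, ts_threshold = 0.9) {
  m <- as.matrix(profile[setdiff(names(profile), "gene_id")])
  if (ncol(m) < 2) stop("need at least 2 tissues", call. = FALSE)
  if (any(m < 0)) stop("profiles must be non-negative", call. = FALSE)
  maxs <- apply(m, 1, max)
  zero <- maxs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s) excluded (tau undefined)",
            call. = FALSE)
  }
  tau <- rowSums(1 - m / ifelse(maxs == 0, NA, maxs)) / (ncol(m) - 1)
  out <- tibble::tibble(gene_id = profile$gene_id, tau = tau,
                        is_ts = tau > ts_threshold)[!zero, ]
  attr(out, "excluded") <- profile$gene_id[zero]
  out
}

#' Standardize expression profiles per gene
#'
#' Centers and scales each gene's profile to mean 0, sd 1 across tissues —
#' the convention for pattern clustering, where shape rather than level is
#' compared. Zero-variance genes are dropped with a warning.
#'
#' @param profile Tibble from [tissue_means()].
#' @return Tibble of the same shape (minus dropped genes).
#' @export
standardize_profile <- function(profile) {
  cols <- setdiff(names(profile), "gene_id")
  m <- as.matrix(profile[cols])
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before standardization",
            call. = FALSE)
  }
  keep <- sds > 0
  m <- t(scale(t(m[keep, , drop = FALSE])))
  out <- tibble::tibble(gene_id = profile$gene_id[keep])
  out[cols] <- as.data.frame(m)
  out
}

#' Fuzzy c-means clustering of expression patterns
#'
#' Soft clustering of standardized multi-tissue profiles: each gene gets a
#' membership in every cluster (rows of the membership matrix sum to 1), so
#' noisy genes are not forced into hard assignments and the strength of a
#' gene's association with a pattern is retained. The standard iteration is
#' used: centroids are membership-weighted means with weights `u^m`, and
#' memberships are inverse-distance ratios
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`. A gene coincident with a
#' centroid takes membership 1 there (the limit rule). Iteration stops when
#' the largest centroid shift drops below `tol`.
#'
#' @param profile Standardized profile tibble ([standardize_profile()]).
#' @param centers Number of clusters c >= 2 (default 8, the operating point
#'   for multi-tissue lung-module patterns).
#' @param m Fuzzifier > 1 (default 2).
#' @param seed Seed for the centroid initialization (random distinct genes);
#'   fixed by default for reproducibility.
#' @param tol Convergence tolerance on the centroid shift.
#' @param max_iter Iteration cap.
#' @return Object of class `fuzzy_clustering`: centroids (c x tissue
#'   matrix), `membership` (gene x c matrix, gene ids as rownames),
#'   `objective` (per-iteration value of `sum u^m d^2`), `iterations`,
#'   `converged`, plus the call parameters.
#' @export
fuzzy_cmeans <- function(profile, centers = 8, m = 2, seed = 1,
                         tol = 1e-6, max_iter = 200) {
  if (centers < 2) stop("`centers` must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  cols <- setdiff(names(profile), "gene_id")
  xm <- as.matrix(profile[cols])
  rownames(xm) <- profile$gene_id
  n <- nrow(xm)
  if (n < centers) stop("fewer genes than clusters", call. = FALSE)
  set.seed(seed)
  cent <- xm[sample.int(n, centers), , drop = FALSE]
  rownames(cent) <- paste0("C", seq_len(centers))
  memb_from_dist <- function(d2) {
    u <- matrix(0, n, centers)
    pow <- 1 / (m - 1)
    for (i in seq_len(n)) {
      di <- d2[i, ]
      if (any(di == 0)) {
        u[i, which(di == 0)] <- 1 / sum(di == 0)
      } else {
        w <- (1 / di)^pow
        u[i, ] <- w / sum(w)
      }
    }
    u
  }
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  u <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- outer(rowSums(xm^2), rep(1, centers)) - 2 * xm %*% t(cent) +
      outer(rep(1, n), rowSums(cent^2))
    d2 <- pmax(d2, 0)
    u <- memb_from_dist(d2)
    um <- u^m
    new_cent <- (t(um) %*% xm) / colSums(um)
    shift <- max(abs(new_cent - cent))
    cent <- new_cent
    rownames(cent) <- paste0("C", seq_len(centers))
    d2 <- outer(rowSums(xm^2), rep(1, centers)) - 2 * xm %*% t(cent) +
      outer(rep(1, n), rowSums(cent^2))
    d2 <- pmax(d2, 0)
    objective <- c(objective, sum(u^m * d2))
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(u) <- list(rownames(xm), rownames(cent))
  structure(list(centroids = cent, membership = u, objective = objective,
                 iterations = iter, converged = converged, centers = centers,
                 m = m, seed = seed),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat("<fuzzy_clustering> ", nrow(x$membership), " genes, ", x$centers,
      " clusters, m = ", x$m, ", ", x$iterations, " iterations (",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.fuzzy_clustering <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$membership), times = ncol(x$membership)),
    cluster = rep(colnames(x$membership), each = nrow(x$membership)),
    membership = as.vector(x$membership)
  )
}

#' @export
glance.fuzzy_clustering <- function(x, ...) {
  tibble::tibble(centers = x$centers, m = x$m,
                 iterations = x$iterations, converged = x$converged,
                 objective = x$objective[length(x$objective)])
}

#' Hard cluster assignment from a fuzzy clustering
#' @param x A `fuzzy_clustering`.
#' @return Tibble (gene_id, cluster, membership) keeping each gene's
#'   maximum-membership cluster.
#' @export
hard_clusters <- function(x) {
  stopifnot(inherits(x, "fuzzy_clustering"))
  idx <- max.col(x$membership, ties.method = "first")
  tibble::tibble(
    gene_id = rownames(x$membership),
    cluster = colnames(x$membership)[idx],
    membership = x$membership[cbind(seq_len(nrow(x$membership)), idx)]
  )
}
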