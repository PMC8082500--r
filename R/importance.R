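#' Weights for the composite importance scores
#'
#' The node score combines four components — connectivity, between-condition
#' differential expression, tissue specificity, and the TF indicator — with
#' non-negative weights normalized to sum to 1; the motif score mixes the
#' mean node score and mean edge score of an instance with weight `alpha`.
#' The exact composite is this package's documented reconstruction of a
#' node/motif scoring scheme whose published description lists the
#' components but not the functional form; every weight is exposed.
#'
#' @param connectivity,diffexpr,tsi,tf Node-component weights (>= 0),
#'   default 0.25 each.
#' @param alpha Motif-score mixing weight in \[0, 1\] (default 0.5).
#' @param epsilon Fold-change stabilizer added to both means (default 1).
#' @return A `score_weights` list with the node weights normalized.
#' @export
score_weights <- function(connectivity = 0.25, diffexpr = 0.25,
                          tsi = 0.25, tf = 0.25, alpha = 0.5, epsilon = 1) {
  w <- c(connectivity = connectivity, diffexpr = diffexpr, tsi = tsi,
         tf = tf)
  if (any(w < 0) || sum(w) == 0) {
    stop("node weights must be non-negative and not all zero", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  structure(list(node = w / sum(w), alpha = alpha, epsilon = epsilon),
            class = "score_weights")
}

minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate component (min = max); set to 0 for all nodes",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Composite node importance scores
#'
#' Each network node is scored by
#' `S_node = w_C * C + w_D * D + w_tau * tau + w_TF * 1_TF`, where C is the
#' min-max-normalized mixed-network degree (regulation arcs in + out, plus
#' co-expression edges, each counted once), D the min-max-normalized
#' absolute log2 fold change of the focal tissue's replicate means between
#' the two conditions (epsilon-stabilized), tau the tissue-specificity
#' index, and 1_TF the TF indicator. All components lie in \[0, 1\], so
#' under the default equal weights so does the score. miRNA nodes have no
#' expression profile; their D and tau are set to 0 rather than dropping
#' the nodes.
#'
#' @param net A `mixed_network`.
#' @param x An `expr_set` containing both conditions for every non-miRNA
#'   node.
#' @param tissue Focal tissue for the differential-expression component.
#' @param tsi_table Tibble (gene_id, tau) from [tsi()], covering every
#'   non-miRNA node.
#' @param weights A [score_weights()].
#' @return Tibble (node, degree, c_hat, d_hat, tau, is_tf, s_node), one row
#'   per network node, components exported for auditability.
#' @export
node_scores <- function(net, x, tissue, tsi_table,
                        weights = score_weights()) {
  stopifnot(inherits(net, "mixed_network"), inherits(x, "expr_set"))
  nodes <- net$nodes
  deg <- stats::setNames(rep(0, nrow(nodes)), nodes$node)
  cnt <- table(c(net$edges$from, net$edges$to))
  deg[names(cnt)] <- as.numeric(cnt)
  md <- x$metadata
  conds <- unique(md$condition)
  if (length(conds) != 2) stop("need exactly 2 conditions", call. = FALSE)
  genes <- nodes$node[!nodes$is_mirna]
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) {
    stop("node '", miss[1], "' has no expression profile", call. = FALSE)
  }
  miss_tau <- setdiff(genes, tsi_table$gene_id)
  if (length(miss_tau)) {
    stop("node '", miss_tau[1], "' has no tau value", call. = FALSE)
  }
  eps <- weights$epsilon
  mean_ct <- function(cond) {
    keep <- md$condition == cond & md$tissue == tissue
    rowMeans(x$values[genes, keep, drop = FALSE])
  }
  lfc <- abs(log2((mean_ct(conds[1]) + eps) / (mean_ct(conds[2]) + eps)))
  d_raw <- stats::setNames(rep(0, nrow(nodes)), nodes$node)
  d_raw[genes] <- lfc
  tau <- stats::setNames(rep(0, nrow(nodes)), nodes$node)
  tau[genes] <- tsi_table$tau[match(genes, tsi_table$gene_id)]
  c_hat <- minmax(deg)
  d_hat <- minmax(d_raw)
  w <- weights$node
  s <- w["connectivity"] * c_hat + w["diffexpr"] * d_hat +
    w["tsi"] * tau + w["tf"] * as.numeric(nodes$is_tf)
  tibble::tibble(node = nodes$node, degree = unname(deg),
                 c_hat = unname(c_hat), d_hat = unname(d_hat),
                 tau = unname(tau), is_tf = nodes$is_tf,
                 s_node = unname(s))
}

#' Edge importance scores
#'
#' The score of an edge is its co-expression weight: co-expression edges
#' keep their adjacency value; regulation arcs between expressed genes get
#' the adjacency of their endpoint pair (computed from `a`); miRNA arcs,
#' whose source has no expression profile, get a fixed documented constant.
#'
#' @param net A `mixed_network`.
#' @param a Adjacency matrix covering the expressed network genes.
#' @param mirna_score Constant score for miRNA arcs (default 0.5).
#' @return Tibble (from, to, type, s_edge).
#' @export
edge_scores <- function(net, a, mirna_score = 0.5) {
  stopifnot(inherits(net, "mixed_network"))
  e <- net$edges
  s <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    if (e$type[i] == "mirna_regulation") {
      s[i] <- mirna_score
    } else if (e$type[i] == "coexpression" && !is.na(e$weight[i])) {
      s[i] <- e$weight[i]
    } else {
      if (!(e$from[i] %in% rownames(a)) || !(e$to[i] %in% rownames(a))) {
        stop("no adjacency available for edge ", e$from[i], " -> ", e$to[i],
             call. = FALSE)
      }
      s[i] <- a[e$from[i], e$to[i]]
    }
  }
  tibble::tibble(from = e$from, to = e$to, type = e$type, s_edge = s)
}

#' Motif (size-3 subgraph) importance scores
#'
#' `S_motif = alpha * mean(S_node over the 3 nodes) + (1 - alpha) *
#' mean(S_edge over the instance's edges)`, where the instance's edges are
#' all typed edges of the network among its three nodes.
#'
#' @param net A `mixed_network`.
#' @param instances Tibble (class_id, a, b, c) from
#'   [find_motif_instances()].
#' @param node_scores Tibble from [node_scores()].
#' @param edge_scores Tibble from [edge_scores()].
#' @param alpha Mixing weight (default 0.5).
#' @return `instances` with an `s_motif` column, sorted by decreasing
#'   score (ties by sorted node ids).
#' @export
motif_scores <- function(net, instances, node_scores, edge_scores,
                         alpha = 0.5) {
  stopifnot(inherits(net, "mixed_network"))
  ns <- stats::setNames(node_scores$s_node, node_scores$node)
  s <- vapply(seq_len(nrow(instances)), function(i) {
    tri <- c(instances$a[i], instances$b[i], instances$c[i])
    inside <- edge_scores$from %in% tri & edge_scores$to %in% tri
    es <- edge_scores$s_edge[inside]
    alpha * mean(ns[tri]) + (1 - alpha) * mean(es)
  }, numeric(1))
  out <- dplyr::mutate(instances, s_motif = s)
  key <- vapply(seq_len(nrow(out)), function(i) {
    paste(sort(c(out$a[i], out$b[i], out$c[i])), collapse = "|")
  }, character(1))
  out[order(-out$s_motif, key), ]
}

#' Rank nodes and keep the top fraction
#'
#' Descending sort on the node score (ties by node id), keeping the top
#' `ceiling(fraction * n)` nodes with a Hub/TF type annotation.
#'
#' @param scores Tibble from [node_scores()].
#' @param net The `mixed_network` (for hub/TF/miRNA flags).
#' @param fraction Fraction of nodes to keep (default 0.25).
#' @return Tibble (rank, node, type, s_node).
#' @export
rank_top_nodes <- function(scores, net, fraction = 0.25) {
  stopifnot(inherits(net, "mixed_network"))
  ord <- order(-scores$s_node, scores$node, method = "radix")
  top <- scores[ord, ][seq_len(ceiling(fraction * nrow(scores))), ]
  flags <- net$nodes[match(top$node, net$nodes$node), ]
  type <- dplyr::case_when(
    flags$is_hub & flags$is_tf ~ "Hub & TF",
    flags$is_hub ~ "Hub",
    flags$is_tf ~ "TF",
    flags$is_mirna ~ "miRNA",
    TRUE ~ "TG"
  )
  tibble::tibble(rank = seq_len(nrow(top)), node = top$node, type = type,
                 s_node = top$s_node)
}

#' Extract the top regulating-mutual complex and its co-regulated targets
#'
#' Finds the highest-scoring regulating-mutual (class 10) instance — a
#' mutually connected regulator pair with a shared target — then collects
#' every size-3 instance sharing at least two of its nodes and groups them
#' by co-regulated target, reporting how many motifs each target closes.
#' Ties on the motif score break deterministically by sorted node ids.
#'
#' @param net A `mixed_network`.
#' @param scored_instances Tibble from [motif_scores()] covering (at least)
#'   the class-10 instances; instances of other classes, when present, are
#'   used for the shared-node membership report.
#' @return Object of class `complex_report`: list with `core` (one-row
#'   tibble), `members` (instances sharing >= 2 nodes with the core) and
#'   `targets` (tibble: target, n_motifs). Empty (with a warning) when the
#'   network has no class-10 instance.
#' @export
extract_top_complex <- function(net, scored_instances) {
  cl10 <- scored_instances[scored_instances$class_id == 10, , drop = FALSE]
  if (!nrow(cl10)) {
    warning("no regulating-mutual (class 10) instance in the network",
            call. = FALSE)
    return(structure(list(core = cl10, members = cl10,
                          targets = tibble::tibble(target = character(0),
                                                   n_motifs = integer(0))),
                     class = "complex_report"))
  }
  key <- vapply(seq_len(nrow(cl10)), function(i) {
    paste(sort(c(cl10$a[i], cl10$b[i], cl10$c[i])), collapse = "|")
  }, character(1))
  cl10 <- cl10[order(-cl10$s_motif, key), ]
  core <- cl10[1, ]
  core_nodes <- c(core$a, core$b, core$c)
  shared <- vapply(seq_len(nrow(scored_instances)), function(i) {
    tri <- c(scored_instances$a[i], scored_instances$b[i],
             scored_instances$c[i])
    sum(tri %in% core_nodes)
  }, numeric(1))
  members <- scored_instances[shared >= 2, , drop = FALSE]
  outside <- purrr::map_chr(seq_len(nrow(members)), function(i) {
    tri <- c(members$a[i], members$b[i], members$c[i])
    extra <- setdiff(tri, core_nodes)
    if (length(extra) == 1) extra else NA_character_
  })
  targets <- tibble::tibble(target = outside[!is.na(outside)])
  targets <- dplyr::count(targets, .data$target, name = "n_motifs")
  structure(list(core = core, members = members,
                 targets = dplyr::arrange(targets, dplyr::desc(.data$n_motifs),
                                          .data$target)),
            class = "complex_report")
}

#' @export
print.complex_report <- function(x, ...) {
  if (!nrow(x$core)) {
    cat("<complex_report> empty (no class-10 instance)\n")
    return(invisible(x))
  }
  cat("<complex_report> core: ", x$core$a, "-", x$core$b, " -> ", x$core$c,
      " (S_motif = ", signif(x$core$s_motif, 4), ")\n",
      "  ", nrow(x$members), " member instance(s), ",
      nrow(x$targets), " co-regulated target(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.complex_report <- function(x, ...) x$targets
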