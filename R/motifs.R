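# Three-node (triad) machinery. A triad on labeled nodes {1,2,3} is coded as
# a 6-bit integer over the ordered pairs (1,2),(1,3),(2,1),(2,3),(3,1),(3,2);
# isomorphism classes are found by minimizing the code over the 6 node
# permutations. The 13 weakly connected classes are indexed in the standard
# significance-profile order, with FFL = 7, Regulated mutual = 9, Regulating
# mutual = 10 and Clique = 13.

.triad_env <- new.env(parent = emptyenv())

triad_pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))

triad_rep_arcs <- list(
  `1` = rbind(c(1, 2), c(1, 3)),                                  # V-out
  `2` = rbind(c(1, 2), c(2, 3)),                                  # 3-chain
  `3` = rbind(c(1, 3), c(2, 3)),                                  # V-in
  `4` = rbind(c(1, 2), c(2, 1), c(3, 1)),                         # mutual V-in
  `5` = rbind(c(1, 2), c(2, 1), c(1, 3)),                         # mutual V-out
  `6` = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),                # double mutual
  `7` = rbind(c(1, 2), c(1, 3), c(2, 3)),                         # FFL
  `8` = rbind(c(1, 2), c(2, 3), c(3, 1)),                         # 3-loop
  `9` = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 2)),                # regulated mutual
  `10` = rbind(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),               # regulating mutual
  `11` = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 1)),               # cycle mutual
  `12` = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),      # semi clique
  `13` = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)) # clique
)

triad_class_names <- c("V-out", "3-chain", "V-in", "Mutual V-in",
                       "Mutual V-out", "Double mutual", "FFL", "3-loop",
                       "Regulated mutual", "Regulating mutual",
                       "Cycle mutual", "Semi clique", "Clique")

arcs_to_code <- function(arcs) {
  code <- 0L
  for (r in seq_len(nrow(arcs))) {
    t <- which(triad_pairs[, 1] == arcs[r, 1] &
                 triad_pairs[, 2] == arcs[r, 2])
    code <- bitwOr(code, bitwShiftL(1L, t - 1L))
  }
  code
}

triad_lookup <- function() {
  if (!is.null(.triad_env$lookup)) return(.triad_env$lookup)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # bit t of the permuted code comes from bit bitmap[s, t] of the original
  bitmap <- matrix(0L, 6, 6)
  for (s in seq_len(6)) {
    for (t in seq_len(6)) {
      src <- c(perms[s, triad_pairs[t, 1]], perms[s, triad_pairs[t, 2]])
      bitmap[s, t] <- which(triad_pairs[, 1] == src[1] &
                              triad_pairs[, 2] == src[2])
    }
  }
  codes <- 0:63
  bits <- sapply(0:5, function(b) bitwAnd(bitwShiftR(codes, b), 1L))
  recoded <- sapply(seq_len(6), function(s) {
    as.integer(bits[, bitmap[s, ]] %*% 2L^(0:5))
  })
  canonical <- apply(recoded, 1, min)
  pair_edge <- cbind(bits[, 1] | bits[, 3], bits[, 2] | bits[, 5],
                     bits[, 4] | bits[, 6])
  connected <- rowSums(pair_edge) >= 2
  rep_codes <- vapply(triad_rep_arcs, arcs_to_code, integer(1))
  rep_canon <- canonical[rep_codes + 1]
  if (anyDuplicated(rep_canon) || any(!connected[rep_codes + 1]) ||
      length(unique(canonical[connected])) != 13) {
    stop("internal error: triad class table is inconsistent")  # nocov
  }
  class_of <- integer(64)
  for (k in seq_len(13)) class_of[canonical == rep_canon[k]] <- k
  class_of[!connected] <- 0L
  .triad_env$lookup <- list(
    perms = perms, bitmap = bitmap, canonical = canonical,
    connected = connected, class_of_code = class_of, rep_codes = rep_codes,
    recoded = recoded
  )
  .triad_env$lookup
}

#' The 13 connected triad classes
#'
#' Enumerates the isomorphism classes of weakly connected 3-node digraphs
#' in the standard significance-profile ordering: FFL is class 7, Regulated
#' mutual (one regulator targeting a mutually connected pair) class 9,
#' Regulating mutual (a mutually connected regulator pair sharing a target)
#' class 10, and the all-mutual Clique class 13. Each row gives a canonical
#' representative on nodes A, B, C.
#'
#' @return Tibble (class_id, name, n_arcs, representative).
#' @export
triad_classes <- function() {
  reps <- vapply(triad_rep_arcs, function(a) {
    paste(paste0(LETTERS[a[, 1]], "->", LETTERS[a[, 2]]), collapse = " ")
  }, character(1))
  tibble::tibble(class_id = 1:13, name = triad_class_names,
                 n_arcs = vapply(triad_rep_arcs, nrow, integer(1)),
                 representative = unname(reps))
}

#' Count triad isomorphism classes by brute-force enumeration
#'
#' Enumerates all 64 labeled 3-node digraphs, groups them by isomorphism,
#' and counts classes: 13 weakly connected classes, 16 in total (adding the
#' empty triad and the two disconnected ones), and 5 connected classes that
#' contain no mutual dyad (the purely directed triads).
#'
#' @param scope One of `"connected"` (default), `"all"`, `"no_mutual"`.
#' @return Integer count.
#' @export
count_triad_classes <- function(scope = c("connected", "all", "no_mutual")) {
  scope <- match.arg(scope)
  lk <- triad_lookup()
  codes <- 0:63
  keep <- switch(scope,
    connected = lk$connected,
    all = rep(TRUE, 64),
    no_mutual = {
      bits <- sapply(0:5, function(b) bitwAnd(bitwShiftR(codes, b), 1L))
      no_mut <- !((bits[, 1] & bits[, 3]) | (bits[, 2] & bits[, 5]) |
                    (bits[, 4] & bits[, 6]))
      lk$connected & no_mut
    })
  length(unique(lk$canonical[keep]))
}

#' Classify a 3-node arc set into its triad class
#'
#' @param arcs Either a 3 x 3 0/1 adjacency matrix or a data frame with
#'   columns `from`, `to` over at most 3 nodes.
#' @param nodes Optional node set (length 3) when `arcs` omits isolated
#'   nodes.
#' @return Integer class id 1-13 for a weakly connected triad, `0` for the
#'   empty triad, `NA` for a non-empty but disconnected one. Self-arcs are
#'   rejected.
#' @export
classify_triad <- function(arcs, nodes = NULL) {
  if (is.matrix(arcs) && nrow(arcs) == 3 && ncol(arcs) == 3) {
    m <- arcs != 0
    if (any(diag(m))) stop("self-arcs are not allowed", call. = FALSE)
  } else {
    arcs <- as.data.frame(arcs)
    nodes <- if (is.null(nodes)) sort(unique(c(arcs$from, arcs$to))) else
      sort(nodes)
    if (length(nodes) > 3) stop("more than 3 nodes", call. = FALSE)
    if (length(nodes) < 3) {
      nodes <- c(nodes, paste0(".pad", seq_len(3 - length(nodes))))
    }
    m <- matrix(FALSE, 3, 3, dimnames = list(nodes, nodes))
    if (nrow(arcs)) {
      if (any(arcs$from == arcs$to)) {
        stop("self-arcs are not allowed", call. = FALSE)
      }
      m[cbind(match(arcs$from, nodes), match(arcs$to, nodes))] <- TRUE
    }
  }
  code <- sum(m[triad_pairs] * 2L^(0:5))
  lk <- triad_lookup()
  if (code == 0) return(0L)
  if (!lk$connected[code + 1]) return(NA_integer_)
  lk$class_of_code[code + 1]
}

as_directed_arcs <- function(g) {
  if (inherits(g, "mixed_network")) return(directify(g))
  if (inherits(g, "igraph")) {
    df <- igraph::as_data_frame(g, what = "edges")[, 1:2]
    names(df) <- c("from", "to")
    if (!igraph::is_directed(g)) {
      df <- rbind(df, data.frame(from = df$to, to = df$from))
    }
    out <- tibble::as_tibble(unique(df))
    attr(out, "nodes") <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
    return(out)
  }
  out <- tibble::as_tibble(as.data.frame(g)[, c("from", "to")])
  out$from <- as.character(out$from)
  out$to <- as.character(out$to)
  if (is.null(attr(out, "nodes"))) {
    attr(out, "nodes") <- sort(unique(c(out$from, out$to)))
  }
  out
}

#' Turn a mixed network into a directed arc set
#'
#' A directed-triad census needs a fully directed graph: each undirected
#' co-expression edge becomes a mutual arc pair, regulation arcs are kept,
#' and parallel duplicates are collapsed. When a pair carries both a
#' regulation arc and a co-expression edge, the default (`collapse =
#' "mutual"`) lets the co-expression edge complete the pair into a mutual
#' dyad; `collapse = "keep_arc"` instead discards the co-expression edge
#' and keeps only the directed arc.
#'
#' @param net A `mixed_network`.
#' @param collapse `"mutual"` (default) or `"keep_arc"`.
#' @return Tibble (from, to) of directed arcs with the node set in
#'   attribute `nodes`.
#' @export
directify <- function(net, collapse = c("mutual", "keep_arc")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(net, "mixed_network"))
  reg <- net$edges[net$edges$directed, c("from", "to")]
  co <- net$edges[!net$edges$directed, c("from", "to")]
  if (collapse == "keep_arc" && nrow(co)) {
    pair_reg <- unique(c(paste(reg$from, reg$to), paste(reg$to, reg$from)))
    co <- co[!(paste(co$from, co$to) %in% pair_reg), , drop = FALSE]
  }
  arcs <- rbind(reg, co, data.frame(from = co$to, to = co$from))
  arcs <- dplyr::distinct(tibble::as_tibble(arcs))
  arcs <- dplyr::arrange(arcs, .data$from, .data$to)
  attr(arcs, "nodes") <- net$nodes$node
  arcs
}

triad_code_of_triples <- function(A, triples) {
  i <- triples[, 1]; j <- triples[, 2]; k <- triples[, 3]
  A[cbind(i, j)] + 2L * A[cbind(i, k)] + 4L * A[cbind(j, i)] +
    8L * A[cbind(j, k)] + 16L * A[cbind(k, i)] + 32L * A[cbind(k, j)]
}

#' Triad census of a directed (or mixed) network
#'
#' Counts every weakly connected node triple by isomorphism class.
#' Enumeration is neighbourhood-based — every connected triple has at least
#' one node adjacent (in the undirected union graph) to both others, so
#' candidate triples are generated from each node's neighbour pairs and
#' deduplicated — which matches the exhaustive all-triples count without
#' visiting the full C(n,3) grid on sparse graphs.
#'
#' @param g A `mixed_network` (directified with the default collapse rule),
#'   a directed `igraph`, or a data frame of arcs (`from`, `to`).
#' @param instances Also return the classified triples?
#' @return Tibble (class_id, name, count) over all 13 classes, with
#'   attributes `n_connected_triples` and (optionally) `instances`, a
#'   tibble (class_id, n1, n2, n3) with nodes in sorted order.
#' @export
triad_census <- function(g, instances = FALSE) {
  arcs <- as_directed_arcs(g)
  nodes <- attr(arcs, "nodes")
  n <- length(nodes)
  lk <- triad_lookup()
  counts <- integer(13)
  trip <- NULL
  cls <- integer(0)
  if (n >= 3 && nrow(arcs)) {
    if (any(arcs$from == arcs$to)) stop("self-arcs are not allowed",
                                        call. = FALSE)
    A <- matrix(0L, n, n)
    fi <- match(arcs$from, nodes)
    ti <- match(arcs$to, nodes)
    A[cbind(fi, ti)] <- 1L
    U <- (A + t(A)) > 0
    cand <- list()
    for (j in seq_len(n)) {
      nb <- which(U[j, ])
      if (length(nb) < 2) next
      pr <- utils::combn(nb, 2)
      cand[[length(cand) + 1]] <- cbind(pr[1, ], j, pr[2, ])
    }
    if (length(cand)) {
      tr <- do.call(rbind, cand)
      s1 <- pmin(tr[, 1], tr[, 2], tr[, 3])
      s3 <- pmax(tr[, 1], tr[, 2], tr[, 3])
      tr <- cbind(s1, tr[, 1] + tr[, 2] + tr[, 3] - s1 - s3, s3)
      key <- (tr[, 1] - 1) * n * n + (tr[, 2] - 1) * n + tr[, 3]
      tr <- tr[!duplicated(key), , drop = FALSE]
      codes <- triad_code_of_triples(A, tr)
      cls <- lk$class_of_code[codes + 1]
      counts <- tabulate(cls, nbins = 13)
      trip <- tr
    }
  }
  out <- tibble::tibble(class_id = 1:13, name = triad_class_names,
                        count = counts)
  attr(out, "n_connected_triples") <- sum(counts)
  if (instances) {
    inst <- if (is.null(trip)) {
      tibble::tibble(class_id = integer(0), n1 = character(0),
                     n2 = character(0), n3 = character(0))
    } else {
      tibble::tibble(class_id = cls, n1 = nodes[trip[, 1]],
                     n2 = nodes[trip[, 2]], n3 = nodes[trip[, 3]])
    }
    attr(out, "instances") <- dplyr::arrange(inst, .data$class_id,
                                             .data$n1, .data$n2, .data$n3)
  }
  out
}

#' Find the instances of one triad class, with role assignment
#'
#' Returns every node triple of the requested class. Roles `a`, `b`, `c`
#' follow the class's canonical representative (see [triad_classes()]): for
#' the FFL, `a` is the top regulator, `b` the intermediate and `c` the
#' target; for Regulating mutual, `a` and `b` are the mutual regulators and
#' `c` the shared target. Symmetric classes are reported once with the
#' lexicographically smallest valid role assignment.
#'
#' @param g As in [triad_census()].
#' @param class_id Triad class, 1-13.
#' @param census Optional precomputed [triad_census()] result (with
#'   `instances = TRUE`) for the same graph, to avoid recomputation.
#' @return Tibble (class_id, a, b, c).
#' @export
find_motif_instances <- function(g, class_id, census = NULL) {
  stopifnot(class_id %in% 1:13)
  cen <- if (is.null(census)) triad_census(g, instances = TRUE) else census
  inst <- attr(cen, "instances")
  inst <- inst[inst$class_id == class_id, , drop = FALSE]
  if (!nrow(inst)) {
    return(tibble::tibble(class_id = integer(0), a = character(0),
                          b = character(0), c = character(0)))
  }
  arcs <- as_directed_arcs(g)
  lk <- triad_lookup()
  rep_code <- lk$rep_codes[class_id]
  pair_set <- unique(paste(arcs$from, arcs$to))
  roles <- purrr::pmap_dfr(inst, function(class_id, n1, n2, n3) {
    tri <- c(n1, n2, n3)
    m <- matrix(FALSE, 3, 3)
    for (p in seq_len(6)) {
      m[triad_pairs[p, 1], triad_pairs[p, 2]] <-
        paste(tri[triad_pairs[p, 1]], tri[triad_pairs[p, 2]]) %in% pair_set
    }
    code <- sum(m[triad_pairs] * 2L^(0:5))
    for (s in seq_len(nrow(lk$perms))) {
      if (lk$recoded[code + 1, s] == rep_code) {
        # permuted code equals the representative: role r is node perms[s, r]
        asg <- tri[lk$perms[s, ]]
        return(tibble::tibble(class_id = class_id, a = asg[1], b = asg[2],
                              c = asg[3]))
      }
    }
    stop("internal error: no role assignment found")  # nocov
  })
  dplyr::arrange(roles, .data$a, .data$b, .data$c)
}

#' Degree-preserving randomization of a directed network
#'
#' Produces a null network preserving every node's in-degree, out-degree
#' and mutual-edge count exactly: single (asymmetric) arcs are switched
#' only among single arcs, mutual dyads only among mutual dyads (as units),
#' and a proposed switch is rejected if it would create a self-arc, a
#' duplicate, or convert a single arc into a mutual dyad (or vice versa).
#'
#' @param g As in [triad_census()] (a directed arc set).
#' @param switches_per_arc Attempted switches per switchable unit
#'   (default 100, a standard burn-in).
#' @param seed Optional seed for this randomization.
#' @return Tibble (from, to) of arcs with the original node set in
#'   attribute `nodes`.
#' @export
randomize_network <- function(g, switches_per_arc = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arcs <- as_directed_arcs(g)
  nodes <- attr(arcs, "nodes")
  n <- length(nodes)
  fi <- match(arcs$from, nodes)
  ti <- match(arcs$to, nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(fi, ti)] <- TRUE
  key <- paste(pmin(fi, ti), pmax(fi, ti))
  is_mutual <- A[cbind(ti, fi)]
  singles <- cbind(fi, ti)[!is_mutual, , drop = FALSE]
  mut <- unique(cbind(pmin(fi, ti), pmax(fi, ti))[is_mutual, , drop = FALSE])
  ns <- nrow(singles)
  nm <- nrow(mut)
  if (ns < 2 && nm < 2) {
    warning("too few arcs to switch; returning a copy", call. = FALSE)
    return(arcs)
  }
  if (ns >= 2) {
    for (it in seq_len(switches_per_arc * ns)) {
      pick <- sample.int(ns, 2)
      a <- singles[pick[1], 1]; b <- singles[pick[1], 2]
      c_ <- singles[pick[2], 1]; d <- singles[pick[2], 2]
      if (a == d || c_ == b) next
      if (A[a, d] || A[c_, b] || A[d, a] || A[b, c_]) next
      A[a, b] <- FALSE; A[c_, d] <- FALSE
      A[a, d] <- TRUE; A[c_, b] <- TRUE
      singles[pick[1], 2] <- d
      singles[pick[2], 2] <- b
    }
  }
  if (nm >= 2) {
    for (it in seq_len(switches_per_arc * nm)) {
      pick <- sample.int(nm, 2)
      u1 <- mut[pick[1], 1]; v1 <- mut[pick[1], 2]
      u2 <- mut[pick[2], 1]; v2 <- mut[pick[2], 2]
      if (length(unique(c(u1, v1, u2, v2))) < 4) next
      if (stats::runif(1) < 0.5) {
        p1 <- c(u1, v2); p2 <- c(u2, v1)
      } else {
        p1 <- c(u1, u2); p2 <- c(v1, v2)
      }
      if (A[p1[1], p1[2]] || A[p1[2], p1[1]] ||
          A[p2[1], p2[2]] || A[p2[2], p2[1]]) next
      A[u1, v1] <- FALSE; A[v1, u1] <- FALSE
      A[u2, v2] <- FALSE; A[v2, u2] <- FALSE
      A[p1[1], p1[2]] <- TRUE; A[p1[2], p1[1]] <- TRUE
      A[p2[1], p2[2]] <- TRUE; A[p2[2], p2[1]] <- TRUE
      mut[pick[1], ] <- c(min(p1), max(p1))
      mut[pick[2], ] <- c(min(p2), max(p2))
    }
  }
  idx <- which(A, arr.ind = TRUE)
  out <- tibble::tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
  out <- dplyr::arrange(out, .data$from, .data$to)
  attr(out, "nodes") <- nodes
  out
}

#' Z scores, significance profile and empirical p from a null ensemble
#'
#' For each triad class, `Z = (count_real - mean_null) / sd_null` (sample
#' sd over the ensemble; classes with zero null sd get Z = 0 and are
#' flagged), the significance profile `SP = Z / ||Z||_2` (unit Euclidean
#' length whenever any Z is nonzero), and empirical over-/under-
#' representation p-values at resolution `1/n_random`, with add-one
#' corrected variants.
#'
#' @param real Census tibble from [triad_census()] (or a length-13 count
#'   vector).
#' @param null_counts Matrix of null census counts, one row per random
#'   network, 13 columns.
#' @return Object of class `triad_significance`: a tibble (class_id, name,
#'   count, null_mean, null_sd, z, sp, p_over, p_under, p_over_corrected,
#'   p_under_corrected, degenerate) with attribute `n_random`.
#' @export
significance_from_counts <- function(real, null_counts) {
  counts <- if (is.data.frame(real)) real$count else as.numeric(real)
  stopifnot(length(counts) == 13, ncol(null_counts) == 13)
  nr <- nrow(null_counts)
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2, stats::sd)
  degenerate <- sdv == 0
  z <- ifelse(degenerate, 0, (counts - mu) / sdv)
  nz <- sqrt(sum(z^2))
  sp <- if (nz > 0) z / nz else z
  p_over <- colMeans(sweep(null_counts, 2, counts, ">=") * 1)
  p_under <- colMeans(sweep(null_counts, 2, counts, "<=") * 1)
  out <- tibble::tibble(
    class_id = 1:13, name = triad_class_names, count = counts,
    null_mean = mu, null_sd = sdv, z = z, sp = sp,
    p_over = p_over, p_under = p_under,
    p_over_corrected = (p_over * nr + 1) / (nr + 1),
    p_under_corrected = (p_under * nr + 1) / (nr + 1),
    degenerate = degenerate
  )
  attr(out, "n_random") <- nr
  class(out) <- c("triad_significance", class(out))
  out
}

#' Triad significance profile against a degree-preserving null ensemble
#'
#' Runs the triad census on the real network and on `n_random` randomized
#' networks (each independently switched from the real one, preserving
#' in/out/mutual degree sequences), then computes per-class Z scores, the
#' length-normalized significance profile and empirical p-values.
#'
#' @param g As in [triad_census()].
#' @param n_random Number of random networks (default 1000; the full-size
#'   operating point is 10000).
#' @param switches_per_arc Switching burn-in per network.
#' @param seed Seed for the ensemble.
#' @return A `triad_significance` tibble (see
#'   [significance_from_counts()]), with the null count matrix in
#'   attribute `null_counts`.
#' @export
triad_significance <- function(g, n_random = 1000, switches_per_arc = 100,
                               seed = 1) {
  arcs <- as_directed_arcs(g)
  real <- triad_census(arcs)
  set.seed(seed)
  null_counts <- matrix(0L, n_random, 13)
  for (r in seq_len(n_random)) {
    rg <- randomize_network(arcs, switches_per_arc = switches_per_arc)
    null_counts[r, ] <- triad_census(rg)$count
  }
  out <- significance_from_counts(real, null_counts)
  attr(out, "null_counts") <- null_counts
  out
}

#' @export
tidy.triad_significance <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' @export
glance.triad_significance <- function(x, ...) {
  tibble::tibble(n_random = attr(x, "n_random"),
                 n_connected_triples = sum(x$count),
                 sp_norm = sqrt(sum(x$sp^2)))
}
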