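# Shared fixtures and independent oracles used across the suite.

# a reduced study configuration for unit tests that do not need the full
# 500-gene default
small_cfg <- function(n_genes = 120, seed = 1, ...) {
  sim_config(n_genes = n_genes,
             modules = list(list(size = 30, tissue = "lung"),
                            list(size = 20, tissue = "muscle")),
             n_tfs = 5, n_mirnas = 2, n_ts_per_tissue = 2,
             seed = seed, ...)
}

# small expression set with explicit values
toy_expr <- function(values = NULL, tissues = c("lung", "lung", "liver",
                                                "liver")) {
  if (is.null(values)) {
    values <- matrix(c(1, 2, 3, 4,
                       4, 3, 2, 1,
                       1, 1, 1, 1), 3, 4, byrow = TRUE)
  }
  n <- ncol(values)
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("s", seq_len(n)))
  md <- tibble::tibble(sample_id = colnames(values), condition = "A",
                       tissue = tissues[seq_len(n)],
                       replicate = stats::ave(seq_len(n),
                                              tissues[seq_len(n)],
                                              FUN = seq_along))
  expression_set(values, md)
}

# random directed arc set on n named nodes (no self-arcs)
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  arcs <- tibble::as_tibble(pairs[stats::runif(nrow(pairs)) < p, ])
  attr(arcs, "nodes") <- nodes
  arcs
}

# exhaustive all-triples triad census: enumerates every C(n,3) triple and
# classifies its induced subgraph, independently of the neighbourhood-based
# enumeration inside triad_census()
brute_triad_census <- function(arcs, nodes) {
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(arcs)) {
    A[cbind(match(arcs$from, nodes), match(arcs$to, nodes))] <- 1L
  }
  counts <- integer(13)
  if (n < 3) return(counts)
  cmb <- utils::combn(n, 3)
  for (i in seq_len(ncol(cmb))) {
    k <- classify_triad(A[cmb[, i], cmb[, i]])
    if (!is.na(k) && k > 0) counts[k] <- counts[k] + 1L
  }
  counts
}

# in/out/mutual degree sequences of an arc set
degree_signature <- function(arcs, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(match(arcs$from, nodes), match(arcs$to, nodes))] <- TRUE
  M <- A & t(A)
  list(out = rowSums(A & !M), inn = colSums(A & !M), mut = rowSums(M))
}

# brute-force network topology concepts, written as literal nested sums
brute_concepts <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- numeric(n)
  for (i in 1:n) for (j in 1:n) if (j != i) k[i] <- k[i] + a[i, j]
  dens <- 0
  for (i in 1:n) for (j in 1:n) if (j != i) dens <- dens + a[i, j]
  dens <- dens / (n * (n - 1))
  cc <- numeric(n)
  for (i in 1:n) {
    num <- 0
    for (j in 1:n) for (u in 1:n) {
      if (j != i && u != i && u != j) num <- num + a[i, j] * a[j, u] * a[u, i]
    }
    s1 <- 0; s2 <- 0
    for (j in 1:n) if (j != i) { s1 <- s1 + a[i, j]; s2 <- s2 + a[i, j]^2 }
    den <- s1^2 - s2
    cc[i] <- if (den > 0) num / den else 0
  }
  cl <- n / (n - 2) * (max(k) / (n - 1) - dens)
  vk <- mean(k^2) - mean(k)^2
  hg <- if (mean(k) > 0) sqrt(vk) / mean(k) else 0
  c(density = dens, mcc = mean(cc), centralization = cl, heterogeneity = hg)
}

# exhaustive PWM window scoring: every window on both strands, by direct
# per-position probability lookups
brute_pwm_hits <- function(p, seq, threshold) {
  bases <- c(A = 1, C = 2, G = 3, T = 4)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
  hits <- list()
  L <- p$length
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    if (nchar(s) < L) next
    for (start in 1:(nchar(s) - L + 1)) {
      w <- substr(s, start, start + L - 1)
      sc <- 0
      for (pos in 1:L) {
        sc <- sc + p$log_odds[bases[[substr(w, pos, pos)]], pos]
      }
      rel <- (sc - p$score_min) / (p$score_max - p$score_min)
      if (rel >= threshold) {
        pos0 <- if (strand == "+") start - 1 else nchar(seq) - start - L + 1
        hits[[length(hits) + 1]] <- data.frame(position = pos0,
                                               strand = strand,
                                               rel_score = rel)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), strand = character(0),
                      rel_score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), ]
}
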