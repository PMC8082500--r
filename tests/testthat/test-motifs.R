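test_that("triad class combinatorics come out of brute-force enumeration", {
  expect_equal(count_triad_classes("connected"), 13)
  expect_equal(count_triad_classes("all"), 16)
  expect_equal(count_triad_classes("no_mutual"), 5)
  tc <- triad_classes()
  expect_equal(nrow(tc), 13)
  expect_equal(tc$name[c(7, 9, 10, 13)],
               c("FFL", "Regulated mutual", "Regulating mutual", "Clique"))
})

test_that("classification matches the anchored class definitions", {
  # FFL: A regulates B and C, B regulates C
  expect_equal(classify_triad(data.frame(from = c("A", "A", "B"),
                                         to = c("B", "C", "C"))), 7L)
  # Regulating mutual: mutual A-B pair sharing target C
  expect_equal(classify_triad(data.frame(from = c("A", "B", "A", "B"),
                                         to = c("B", "A", "C", "C"))), 10L)
  # Regulated mutual: A regulates the mutually connected B, C
  expect_equal(classify_triad(data.frame(from = c("A", "A", "B", "C"),
                                         to = c("B", "C", "C", "B"))), 9L)
  # Clique: all pairs mutual
  expect_equal(classify_triad(
    data.frame(from = c("A", "B", "A", "C", "B", "C"),
               to = c("B", "A", "C", "A", "C", "B"))), 13L)
  # 3-loop
  expect_equal(classify_triad(data.frame(from = c("A", "B", "C"),
                                         to = c("B", "C", "A"))), 8L)
  # empty and disconnected
  expect_equal(classify_triad(matrix(0, 3, 3)), 0L)
  m <- matrix(0, 3, 3); m[1, 2] <- 1
  expect_true(is.na(classify_triad(m)))
  m[1, 1] <- 1
  expect_error(classify_triad(m), "self-arc")
})

test_that("classification is invariant under node relabeling for all 64 codes", {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (code in 0:63) {
    m <- matrix(0L, 3, 3)
    for (b in 1:6) if (bitwAnd(bitwShiftR(code, b - 1L), 1L))
      m[pairs[b, 1], pairs[b, 2]] <- 1L
    ref <- classify_triad(m)
    for (s in 1:6) {
      mp <- m[perms[s, ], perms[s, ]]
      expect_identical(classify_triad(mp), ref)
    }
  }
})

test_that("each canonical representative counts once in its own class", {
  tc <- triad_classes()
  for (k in 1:13) {
    arcs <- strsplit(strsplit(tc$representative[k], " ")[[1]], "->")
    df <- data.frame(from = vapply(arcs, `[`, "", 1),
                     to = vapply(arcs, `[`, "", 2))
    cen <- triad_census(df)
    expect_equal(cen$count[k], 1)
    expect_equal(sum(cen$count), 1)
  }
  # empty graph: all counts zero
  e <- triad_census(tibble::tibble(from = character(0), to = character(0)))
  expect_true(all(e$count == 0))
})

test_that("the census equals the exhaustive all-triples oracle and igraph", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:10) {
    n <- sample(8:25, 1)
    arcs <- random_digraph(n, runif(1, 0.05, 0.25), seed = 1000 + i)
    nodes <- attr(arcs, "nodes")
    cen <- triad_census(arcs)
    expect_equal(cen$count, brute_triad_census(arcs, nodes))
    expect_equal(sum(cen$count), attr(cen, "n_connected_triples"))
    # independent cross-check against the Davis-Leinhardt census
    g <- igraph::graph_from_data_frame(arcs, vertices = nodes)
    dl <- igraph::triad_census(g)
    map <- c(`1` = 4, `3` = 5, `2` = 6, `7` = 9, `8` = 10, `6` = 11,
             `9` = 12, `10` = 13, `11` = 14, `12` = 15, `13` = 16)
    for (k in names(map)) {
      expect_equal(cen$count[as.integer(k)], dl[map[[k]]])
    }
    expect_equal(cen$count[4] + cen$count[5], dl[7] + dl[8])
  }
})

test_that("directify turns co-expression into mutual arcs with collapse", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), module = "M1")
  a <- matrix(0.5, 3, 3, dimnames = list(genes$gene_id, genes$gene_id))
  diag(a) <- 1
  a["g1", "g3"] <- a["g3", "g1"] <- 0.01
  net <- assemble_network(genes,
                          tf_arcs = tibble::tibble(from = "tf1", to = "g1"),
                          a = a, coexpr_cutoff = 0.1, tfs = "tf1")
  arcs <- directify(net)
  # one undirected edge becomes two arcs; the tf arc stays single
  expect_true(all(c("g1 g2", "g2 g1", "g2 g3", "g3 g2", "tf1 g1") %in%
                    paste(arcs$from, arcs$to)))
  expect_equal(nrow(arcs), 5)
  # arc + co-expression on the same pair collapse to a mutual dyad...
  net2 <- assemble_network(genes,
                           tf_arcs = tibble::tibble(from = "g1", to = "g2"),
                           a = a, coexpr_cutoff = 0.1,
                           tfs = "g1")
  arcs2 <- directify(net2)
  expect_true(all(c("g1 g2", "g2 g1") %in% paste(arcs2$from, arcs2$to)))
  # ...unless the co-expression edge is discarded in favour of the arc
  arcs3 <- directify(net2, collapse = "keep_arc")
  expect_true("g1 g2" %in% paste(arcs3$from, arcs3$to))
  expect_false("g2 g1" %in% paste(arcs3$from, arcs3$to))
  # purely directed networks pass through unchanged
  pd <- assemble_network(genes,
                         tf_arcs = tibble::tibble(from = c("tf1", "tf1"),
                                                  to = c("g1", "g2")),
                         tfs = "tf1")
  expect_equal(nrow(directify(pd)), 2)
})

test_that("role assignment follows the canonical representatives", {
  ffl <- find_motif_instances(data.frame(from = c("x", "x", "y"),
                                         to = c("y", "z", "z")), 7)
  expect_equal(nrow(ffl), 1)
  expect_equal(c(ffl$a, ffl$b, ffl$c), c("x", "y", "z"))
  rm10 <- find_motif_instances(data.frame(from = c("p", "q", "p", "q"),
                                          to = c("q", "p", "t", "t")), 10)
  expect_equal(sort(c(rm10$a, rm10$b)), c("p", "q"))
  expect_equal(rm10$c, "t")
  # symmetric clique: reported once, roles in lexicographic order
  cl <- find_motif_instances(
    data.frame(from = c("u", "v", "u", "w", "v", "w"),
               to = c("v", "u", "w", "u", "w", "v")), 13)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$a, cl$b, cl$c), c("u", "v", "w"))
})

test_that("randomization conserves in/out/mutual degrees exactly", {
  set.seed(5)
  for (i in 1:6) {
    n <- sample(10:25, 1)
    arcs <- random_digraph(n, 0.15, seed = 300 + i)
    # add mutual pairs so both switch families run
    extra <- tibble::tibble(from = arcs$to[1:4], to = arcs$from[1:4])
    arcs2 <- dplyr::distinct(dplyr::bind_rows(arcs, extra))
    attr(arcs2, "nodes") <- attr(arcs, "nodes")
    d0 <- degree_signature(arcs2, attr(arcs2, "nodes"))
    for (r in 1:3) {
      rg <- randomize_network(arcs2, switches_per_arc = 5)
      expect_identical(degree_signature(rg, attr(arcs2, "nodes")), d0)
      expect_false(any(paste(rg$from, rg$to) |> duplicated()))
      expect_false(any(rg$from == rg$to))
    }
  }
  # a 2-arc path admits no legal switch: the output is the input
  two <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  attr(two, "nodes") <- c("a", "b", "c")
  cp <- randomize_network(two, seed = 1)
  expect_setequal(paste(cp$from, cp$to), paste(two$from, two$to))
  # a single arc cannot be switched at all: copy with a warning
  one <- tibble::tibble(from = "a", to = "b")
  attr(one, "nodes") <- c("a", "b")
  expect_warning(c1 <- randomize_network(one, seed = 1), "too few")
  expect_equal(paste(c1$from, c1$to), "a b")
})

test_that("switching explores the configuration space uniformly", {
  # three disjoint single arcs admit exactly the 3! = 6 perfect matchings
  # of sources to sinks as degree-preserving states
  base <- tibble::tibble(from = c("a", "c", "e"), to = c("b", "d", "f"))
  attr(base, "nodes") <- c("a", "b", "c", "d", "e", "f")
  # on fully disjoint arcs every proposal succeeds, so one run's state
  # parity is set by its attempt count; alternating odd/even counts samples
  # both parities (real networks reject proposals and mix on their own)
  set.seed(42)
  states <- vapply(1:3000, function(i) {
    rg <- randomize_network(base, switches_per_arc = 2 + i %% 2)
    paste(sort(paste(rg$from, rg$to)), collapse = ";")
  }, character(1))
  tab <- table(states)
  expect_equal(length(tab), 6)
  expect_gt(min(tab) / 3000, 1 / 6 * 0.5)
})

test_that("randomization perturbs the census of structured networks", {
  sim <- simulate_study(sim_config(seed = 3))
  truth <- sim$truth
  net <- assemble_network(truth$modules[, c("gene_id", "module")],
                          tf_arcs = truth$arcs[truth$arcs$type == "tf",
                                               c("from", "to")],
                          tfs = truth$tf_ids)
  arcs <- directify(net)
  real <- triad_census(arcs)$count
  set.seed(7)
  diffs <- vapply(1:10, function(i) {
    sum(triad_census(randomize_network(arcs,
                                       switches_per_arc = 10))$count != real)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("Z scores, SP normalization and empirical p behave as defined", {
  # hand ensemble: real count 4, null mean 2, sd 1 -> Z = 2
  null <- matrix(0, 4, 13)
  null[, 7] <- c(3, 1, 3, 1)   # mean 2
  real <- integer(13); real[7] <- 4
  sg <- significance_from_counts(real, null)
  expect_equal(sg$z[7], (4 - 2) / sd(c(3, 1, 3, 1)))
  # degenerate classes: sd 0 -> Z 0, flagged, p_over counts ties
  expect_true(all(sg$degenerate[-7]))
  expect_true(all(sg$z[-7] == 0))
  expect_equal(sg$p_over[1], 1)  # null counts all equal the real count 0
  expect_equal(sg$p_over[7], 0)
  expect_equal(sg$p_over_corrected[7], 1 / 5)
  # SP has unit norm whenever some Z is nonzero
  expect_equal(sqrt(sum(sg$sp^2)), 1)
  # permuting ensemble members changes nothing
  sg2 <- significance_from_counts(real, null[c(3, 1, 4, 2), ])
  expect_equal(sg2$z, sg$z)
  expect_equal(sg2$sp, sg$sp)
  expect_equal(sg2$p_over, sg$p_over)
})
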