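# a small hand network: tf regulates two module genes that are co-expressed
hand_net <- function() {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), module = "M1")
  a <- matrix(0.73, 3, 3,
              dimnames = list(c("g1", "g2", "tf"), c("g1", "g2", "tf")))
  diag(a) <- 1
  net <- assemble_network(genes,
                          tf_arcs = tibble::tibble(from = c("tf", "tf"),
                                                   to = c("g1", "g2")),
                          mirna_arcs = tibble::tibble(from = "mir",
                                                      to = "g1"),
                          a = a, coexpr_cutoff = 0.1, tfs = "tf",
                          mirnas = "mir")
  list(net = net, a = a)
}

hand_expr <- function() {
  v <- rbind(tf = c(10, 10, 2, 2, 1, 1, 1, 1),
             g1 = c(8, 8, 8, 8, 1, 1, 1, 1),
             g2 = c(6, 6, 6, 6, 2, 2, 2, 2))
  colnames(v) <- paste0("s", 1:8)
  md <- tibble::tibble(sample_id = colnames(v),
                       condition = rep(c("hi", "lo"), c(4, 4)),
                       tissue = rep(c("lung", "liver"), 4),
                       replicate = rep(1:2, 4))
  md$tissue <- c("lung", "lung", "liver", "liver",
                 "lung", "lung", "liver", "liver")
  expression_set(v, md)
}

test_that("node scores combine the four components as documented", {
  h <- hand_net()
  es <- hand_expr()
  tsi_tbl <- tibble::tibble(gene_id = c("tf", "g1", "g2"),
                            tau = c(0.8, 0.1, 0.4))
  ns <- node_scores(h$net, es, "lung", tsi_tbl)
  expect_true(all(ns$s_node >= 0 & ns$s_node <= 1))
  # components are min-max normalized: degrees tf=2, g1=3, g2=2, mir=1
  expect_equal(ns$degree[match(c("tf", "g1", "g2", "mir"), ns$node)],
               c(2, 3, 2, 1))
  expect_equal(ns$c_hat[ns$node == "g1"], 1)
  expect_equal(ns$c_hat[ns$node == "mir"], 0)
  # miRNA nodes carry zero tau and fold change
  expect_equal(ns$tau[ns$node == "mir"], 0)
  expect_equal(ns$d_hat[ns$node == "mir"], 0)
  # hand evaluation of the composite for the tf node
  eps <- 1
  lfc <- function(g) {
    hi <- mean(es$values[g, es$metadata$condition == "hi" &
                           es$metadata$tissue == "lung"])
    lo <- mean(es$values[g, es$metadata$condition == "lo" &
                           es$metadata$tissue == "lung"])
    abs(log2((hi + eps) / (lo + eps)))
  }
  raw <- c(tf = lfc("tf"), g1 = lfc("g1"), g2 = lfc("g2"), mir = 0)
  dhat <- (raw - min(raw)) / diff(range(raw))
  chat <- setNames((c(2, 3, 2, 1) - 1) / 2, c("tf", "g1", "g2", "mir"))
  s_tf <- 0.25 * chat[["tf"]] + 0.25 * dhat[["tf"]] + 0.25 * 0.8 + 0.25 * 1
  expect_equal(ns$s_node[ns$node == "tf"], s_tf)
  # upper and lower bounds: all components maximal / minimal
  s_g2 <- 0.25 * chat[["g2"]] + 0.25 * dhat[["g2"]] + 0.25 * 0.4
  expect_equal(ns$s_node[ns$node == "g2"], s_g2)
})

test_that("node scores are monotone in every component", {
  set.seed(12)
  w <- score_weights()
  for (i in 1:20) {
    comp <- runif(4)
    bumped <- comp
    j <- sample(1:4, 1)
    bumped[j] <- min(1, bumped[j] + runif(1))
    s0 <- sum(w$node * comp)
    s1 <- sum(w$node * bumped)
    expect_gte(s1, s0)
  }
  # weight normalization and the TF-only limit
  wt <- score_weights(connectivity = 0, diffexpr = 0, tsi = 0, tf = 3)
  expect_equal(unname(wt$node), c(0, 0, 0, 1))
  h <- hand_net()
  ns <- node_scores(h$net, hand_expr(), "lung",
                    tibble::tibble(gene_id = c("tf", "g1", "g2"),
                                   tau = c(0, 1, 1)),
                    weights = wt)
  expect_true(all(ns$s_node[ns$is_tf] == 1))
  expect_true(all(ns$s_node[!ns$is_tf] == 0))
  expect_error(score_weights(connectivity = -1), "non-negative")
  expect_error(score_weights(alpha = 2), "alpha")
})

test_that("edge scores are adjacency for expressed pairs, constant for miRNA", {
  h <- hand_net()
  es <- edge_scores(h$net, h$a)
  expect_equal(es$s_edge[es$type == "coexpression"], 0.73)
  expect_equal(es$s_edge[es$type == "mirna_regulation"], 0.5)
  # a perfectly correlated regulated pair at high beta still scores 1
  v <- rbind(tfp = 1:6, tg = 2 * (1:6))
  colnames(v) <- paste0("s", 1:6)
  ap <- adjacency_matrix(v, 20)
  netp <- assemble_network(tibble::tibble(gene_id = "tg", module = "M1"),
                           tf_arcs = tibble::tibble(from = "tfp", to = "tg"),
                           tfs = "tfp")
  expect_equal(edge_scores(netp, ap)$s_edge, 1)
  # independent genes give near-zero scores at beta 20
  set.seed(4)
  vi <- matrix(rnorm(2 * 50), 2, 50,
               dimnames = list(c("tfp", "tg"), paste0("s", 1:50)))
  ai <- adjacency_matrix(vi, 20)
  expect_lt(edge_scores(netp, ai)$s_edge, 1e-6)
})

test_that("motif scores mix node and edge means; hand case checks out", {
  h <- hand_net()
  ns <- tibble::tibble(node = c("tf", "g1", "g2", "mir"),
                       s_node = c(1, 0.5, 0.5, 0))
  esg <- edge_scores(h$net, h$a)
  inst <- find_motif_instances(h$net, 9)   # tf -> (g1 <-> g2)
  expect_equal(nrow(inst), 1)
  ms <- motif_scores(h$net, inst, ns, esg)
  # instance edges: tf->g1 (0.73 via adjacency), tf->g2 (0.73),
  # g1<->g2 co-expression (0.73), mir->g1 excluded? mir is outside the triad
  inside <- esg[esg$from %in% c("tf", "g1", "g2") &
                  esg$to %in% c("tf", "g1", "g2"), ]
  expected <- 0.5 * mean(c(1, 0.5, 0.5)) + 0.5 * mean(inside$s_edge)
  expect_equal(ms$s_motif, expected)
  # the documented worked example
  expect_equal(0.5 * mean(c(1, 0.5, 0.5)) + 0.5 * mean(c(0.8, 0.6)),
               0.5 * (2 / 3) + 0.5 * 0.7)
  # bounds
  expect_equal(0.5 * 1 + 0.5 * 1, 1)
})

test_that("ranking keeps the ceil fraction with deterministic ties", {
  scores <- tibble::tibble(node = sprintf("n%03d", 1:160),
                           s_node = rep(seq(1, 0.05, length.out = 40),
                                        each = 4))
  nodes <- tibble::tibble(node = scores$node, is_tf = FALSE,
                          is_mirna = FALSE, is_hub = FALSE,
                          module = NA_character_)
  net <- structure(list(nodes = nodes,
                        edges = tibble::tibble(from = character(0),
                                               to = character(0),
                                               type = character(0),
                                               weight = numeric(0),
                                               directed = logical(0))),
                   class = "mixed_network")
  top <- rank_top_nodes(scores, net, fraction = 0.25)
  expect_equal(nrow(top), 40)     # ceil(0.25 * 160)
  expect_equal(top$rank, 1:40)
  # ties resolve by node id
  expect_equal(top$node[1:4], sprintf("n%03d", 1:4))
  expect_equal(nrow(rank_top_nodes(scores, net, 1)), 160)
})

test_that("top-complex extraction selects and reports the planted complex", {
  sim <- simulate_study(sim_config(seed = 1))
  fl <- mad_filter(sim$expr)
  truth <- sim$truth
  a <- adjacency_matrix(fl, 6)
  net <- assemble_network(truth$modules[, c("gene_id", "module")],
                          tf_arcs = truth$arcs[truth$arcs$type == "tf",
                                               c("from", "to")],
                          a = a, coexpr_cutoff = 0.1, tfs = truth$tf_ids)
  cen <- triad_census(net, instances = TRUE)
  ns <- node_scores(net, fl, "lung", tsi(tissue_means(fl, "highland")))
  esg <- edge_scores(net, a)
  inst <- dplyr::bind_rows(lapply(c(7, 9, 10), function(k)
    find_motif_instances(net, k, census = cen)))
  ms <- motif_scores(net, inst, ns, esg)
  cx <- extract_top_complex(net, ms)
  planted <- truth$triads[truth$triads$class_id == 10, ][1, ]
  expect_setequal(c(cx$core$a, cx$core$b, cx$core$c),
                  c(planted$a, planted$b, planted$c))
  # co-regulated targets: each shared target closes class-10 + FFL motifs
  shared <- truth$triads$c[truth$triads$class_id == 10][-1]
  expect_true(all(shared %in% cx$targets$target))
  # every member shares at least two core nodes
  core <- c(cx$core$a, cx$core$b, cx$core$c)
  overlap <- mapply(function(x, y, z) sum(c(x, y, z) %in% core),
                    cx$members$a, cx$members$b, cx$members$c)
  expect_true(all(overlap >= 2))

  # no class-10 instance: empty report with a warning
  lone <- assemble_network(tibble::tibble(gene_id = "g1", module = "M1"),
                           tf_arcs = tibble::tibble(from = "tf1", to = "g1"),
                           tfs = "tf1")
  li <- find_motif_instances(lone, 10)
  expect_warning(empty <- extract_top_complex(lone,
                                              dplyr::mutate(li,
                                                            s_motif = numeric(0))),
                 "no regulating-mutual")
  expect_equal(nrow(empty$targets), 0)
})

test_that("equal-score class-10 ties break by sorted node ids", {
  inst <- tibble::tibble(class_id = c(10L, 10L),
                         a = c("z1", "a1"), b = c("z2", "a2"),
                         c = c("z3", "a3"), s_motif = c(0.5, 0.5))
  net <- structure(list(nodes = tibble::tibble(node = character(0)),
                        edges = tibble::tibble()), class = "mixed_network")
  cx <- extract_top_complex(net, inst)
  expect_equal(c(cx$core$a, cx$core$b, cx$core$c), c("a1", "a2", "a3"))
})
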