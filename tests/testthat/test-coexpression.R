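test_that("adjacency is |cor|^beta with valid range and symmetry", {
  sim <- simulate_expression(small_cfg(seed = 1))
  v <- sim$expr$values
  cc <- cor(t(v))
  a2 <- adjacency_matrix(sim$expr, 2)
  off <- row(a2) != col(a2)
  expect_equal(a2[off], (abs(cc)^2)[off])
  # beta = 1 is |cor| exactly
  a1 <- adjacency_matrix(sim$expr, 1)
  expect_equal(a1[off], abs(cc)[off])
  # a correlation of 0.5 at beta 2 gives adjacency 0.25
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5) # cor = ?
  m <- rbind(g1 = x, g2 = x * 0.5 + sqrt(1 - 0.25) * resid(lm(y ~ x)))
  # construct an exact cor 0.5 pair instead
  e <- resid(lm(y ~ x)); e <- e / sd(e); xs <- (x - mean(x)) / sd(x)
  m <- rbind(g1 = xs, g2 = 0.5 * xs + sqrt(0.75) * e)
  colnames(m) <- paste0("s", 1:6)
  expect_equal(cor(m["g1", ], m["g2", ]), 0.5)
  aa <- adjacency_matrix(m + 10, 2) # shift keeps values positive
  expect_equal(aa["g1", "g2"], 0.25)

  # perfectly correlated pair -> adjacency 1 for any beta
  pp <- rbind(g1 = 1:5, g2 = 2 * (1:5) + 3)
  colnames(pp) <- paste0("s", 1:5)
  expect_equal(adjacency_matrix(pp, 7)["g1", "g2"], 1)

  # invariants on random data
  set.seed(3)
  r <- matrix(rexp(40 * 8), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  ar <- adjacency_matrix(r, 6)
  expect_lt(max(abs(ar - t(ar))), 1e-12)
  expect_true(all(ar >= 0 & ar <= 1))

  # zero-variance gene: correlations defined as 0, with a warning
  r[1, ] <- 4
  expect_warning(az <- adjacency_matrix(r, 6), "zero-variance")
  expect_true(all(az[1, -1] == 0))
})

test_that("scale-free fit scores an exact power law near 1", {
  # degree sequence with p(k) proportional to 1/k
  k <- rep(1:50, times = round(6000 / (1:50)))
  expect_gte(scale_free_fit(k), 0.99)
  # an increasing log-log relationship scores negative
  k2 <- rep(1:50, times = round((1:50)))
  expect_lt(scale_free_fit(k2), 0)
  # degenerate: all connectivities equal
  expect_equal(scale_free_fit(rep(3, 100)), 0)
})

test_that("soft-threshold selection picks the smallest passing power", {
  sim <- simulate_expression(small_cfg(150, seed = 2))
  st <- pick_soft_threshold(sim$expr, powers = c(1, 2, 4, 6, 8, 10),
                            r2_goal = 0.5)
  expect_s3_class(st, "soft_threshold")
  expect_equal(nrow(st$report), 6)
  # mean connectivity strictly decreases in beta
  expect_true(all(diff(st$report$mean_k) < 0))
  hit <- st$report$beta[st$report$r_squared >= 0.5]
  if (length(hit)) expect_equal(st$beta, min(hit))
  # a one-power grid selects that power
  expect_equal(pick_soft_threshold(sim$expr, powers = 5)$beta, 5)
})

test_that("topological overlap matches the formula and its limits", {
  # all-zero off-diagonal -> zero overlap
  a0 <- diag(4)
  expect_true(all(tom_similarity(a0)[upper.tri(a0)] == 0))
  # complete triangle -> full overlap
  a1 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a1)[1, 2], 1)
  # hand case: a12 = a13 = 0.5, a23 = 0
  # l23 = a21 * a13 = 0.25; k2 = k3 = 0.5; w23 = (0.25 + 0)/(0.5 + 1) = 1/6
  ah <- diag(3)
  ah[1, 2] <- ah[2, 1] <- 0.5
  ah[1, 3] <- ah[3, 1] <- 0.5
  w <- tom_similarity(ah)
  expect_equal(w[2, 3], 0.25 / 1.5)
  # l12 = 0, k1 = 1, k2 = 0.5 -> w12 = (0 + 0.5)/(0.5 + 1 - 0.5) = 0.5
  expect_equal(w[1, 2], 0.5)
  # symmetry/range on random adjacency
  set.seed(8)
  cc <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)))
  ar <- abs(cc)^3; diag(ar) <- 1
  wr <- tom_similarity(ar)
  expect_lt(max(abs(wr - t(wr))), 1e-12)
  expect_true(all(wr >= 0 & wr <= 1 + 1e-12))
  # unweighted nested-neighbourhood limit: N(1) within N(2), a12 = 1 -> w12
  # = 1 (note TOM >= adjacency is false in general and is not asserted)
  ac <- matrix(0, 4, 4)
  ac[1, 2] <- ac[2, 1] <- 1
  ac[1, 3] <- ac[3, 1] <- 1
  ac[2, 3] <- ac[3, 2] <- 1
  ac[2, 4] <- ac[4, 2] <- 1
  diag(ac) <- 1
  expect_equal(tom_similarity(ac)[1, 2], 1)
})

test_that("module detection separates planted blocks and respects min size", {
  # block-diagonal similarity: two perfect modules
  w <- diag(60)
  w[1:30, 1:30] <- 0.9
  w[31:60, 31:60] <- 0.9
  diag(w) <- 1
  dimnames(w) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
  mm <- detect_modules(w, min_size = 10)
  expect_equal(length(unique(mm$module)), 2)
  expect_equal(length(unique(mm$module[1:30])), 1)
  expect_equal(length(unique(mm$module[31:60])), 1)
  # min size larger than n -> everything unassigned
  mm2 <- detect_modules(w, min_size = 100)
  expect_true(all(mm2$module == "unassigned"))
})

test_that("eigengenes are unit-norm, sign-aligned, and track the factor", {
  sim <- simulate_expression(small_cfg(150, seed = 7))
  truth <- sim$truth$modules
  me <- module_eigengenes(sim$expr, truth[, c("gene_id", "module")])
  expect_equal(colnames(me$values), sort(unique(truth$module)))
  for (m in colnames(me$values)) {
    expect_equal(sum(me$values[, m]^2), 1)
    f <- sim$truth$factors[, m]
    expect_gte(abs(cor(me$values[, m], f)), 0.9)
  }
  # a module of identical genes: eigengene is that standardized profile,
  # variance explained 1, and the sign follows the module mean
  v <- rbind(g1 = c(1, 5, 2, 8), g2 = c(1, 5, 2, 8), g3 = c(1, 5, 2, 8))
  colnames(v) <- paste0("s", 1:4)
  es <- expression_set(v, tibble::tibble(sample_id = colnames(v),
                                         condition = "A", tissue = "lung",
                                         replicate = 1:4))
  one <- module_eigengenes(es, tibble::tibble(gene_id = rownames(v),
                                              module = "M1"))
  expect_equal(unname(one$var_explained["M1"]), 1)
  prof <- scale(c(1, 5, 2, 8))[, 1]
  expect_equal(abs(cor(one$values[, "M1"], prof)), 1)
  expect_gte(cor(one$values[, "M1"], prof), 0)
})

test_that("module merging joins duplicates and leaves opposites alone", {
  sim <- simulate_expression(small_cfg(150, seed = 3))
  truth <- sim$truth$modules[, c("gene_id", "module")]
  # split one planted module artificially in two: eigengene correlation 1
  split <- truth
  p1 <- split$gene_id[split$module == "P1"]
  split$module[split$gene_id %in% p1[1:15]] <- "P1b"
  merged <- merge_close_modules(sim$expr, split, 0.9)
  expect_equal(length(setdiff(unique(merged$module), "unassigned")),
               length(setdiff(unique(truth$module), "unassigned")))
  lab <- merged$module[merged$gene_id %in% p1]
  expect_equal(length(unique(lab)), 1)
  # distinct planted modules (different target tissues) never merge
  same <- merge_close_modules(sim$expr, truth, 0.9)
  expect_equal(length(setdiff(unique(same$module), "unassigned")),
               length(unique(truth$module)))
})

test_that("gene significance reflects tissue restriction", {
  sim <- simulate_expression(sim_config(seed = 1))
  es <- sim$expr
  # a gene expressed only in the focal tissue has GS near 1
  v <- es$values
  v["b0001", ] <- ifelse(es$metadata$tissue == "lung", 50, 0.01)
  es2 <- expression_set(v, es$metadata)
  gs <- gene_significance(es2, "lung", condition = "highland")
  expect_gte(gs$gs[gs$gene_id == "b0001"], 0.99)
  # constant gene -> GS 0
  v["b0002", ] <- 7
  es3 <- expression_set(v, es$metadata)
  gs3 <- gene_significance(es3, "lung", condition = "highland")
  expect_equal(gs3$gs[gs3$gene_id == "b0002"], 0)
  # signed variant keeps direction
  gss <- gene_significance(es2, "lung", condition = "highland",
                           signed = TRUE)
  expect_gt(gss$gs[gss$gene_id == "b0001"], 0)
})

test_that("network concepts match hand values and the brute-force oracle", {
  # complete unweighted graph: density 1, MCC 1, centralization 0,
  # heterogeneity 0
  cg <- matrix(1, 5, 5); diag(cg) <- 0
  nc <- network_concepts(cg)
  expect_equal(nc$density, 1)
  expect_equal(nc$mcc, 1)
  expect_equal(nc$centralization, 0)
  expect_equal(nc$heterogeneity, 0)
  # star on 5 nodes, brute-force oracle
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  bs <- brute_concepts(star)
  ns <- network_concepts(star)
  expect_equal(ns$density, unname(bs["density"]))
  expect_equal(ns$mcc, unname(bs["mcc"]))
  expect_equal(ns$centralization, unname(bs["centralization"]))
  expect_equal(ns$heterogeneity, unname(bs["heterogeneity"]))
  # weighted random matrices agree with the literal-sum oracle
  set.seed(21)
  for (i in 1:5) {
    n <- sample(3:7, 1)
    aw <- matrix(runif(n * n), n, n)
    aw <- (aw + t(aw)) / 2; diag(aw) <- 1
    b <- brute_concepts(aw)
    o <- network_concepts(aw)
    expect_equal(unlist(o[, -1]), b, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(network_concepts(matrix(1, 2, 2)), "3 nodes")
})

test_that("key-module calls require both the p and the median-GS criterion", {
  sim <- simulate_expression(sim_config(seed = 1))
  fl <- mad_filter(sim$expr)
  a <- adjacency_matrix(fl, 6)
  mm <- merge_close_modules(fl, detect_modules(tom_similarity(a)))
  st <- module_stats(fl, mm, a, condition = "highland")
  me <- module_eigengenes(fl, mm)
  km <- key_modules(me, fl, st, condition = "highland")
  # the Bonferroni threshold is alpha / (modules x tissues)
  n_mod <- length(setdiff(unique(mm$module), "unassigned"))
  expect_equal(unique(km$bonferroni), 0.05 / (n_mod * 6))
  expect_true(all(km$is_key == (km$p < km$bonferroni & km$median_gs > 0.8)))
  # a significant p with low GS must not pass, nor high GS with weak p
  expect_false(any(km$is_key[km$median_gs <= 0.8]))
  expect_false(any(km$is_key[km$p >= km$bonferroni]))
})

test_that("hub criteria are inclusive at every boundary", {
  stats <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), module = "M1",
    mm = c(0.95, 0.95, 0.94, rep(0.99, 7)),
    k_within = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
    k_total = 12,
    gs_lung = c(0.8, 0.79, rep(0.9, 8))
  )
  hb <- hub_genes(stats, "lung")
  # ceil(0.2 * 10) = 2 -> ranks 1 and 2 eligible
  expect_true(hb$is_hub[hb$gene_id == "g01"])   # all at threshold
  expect_false(hb$is_hub[hb$gene_id == "g02"])  # gs below 0.8
  expect_false(hb$is_hub[hb$gene_id == "g03"])  # mm below + rank out
  expect_false(any(hb$is_hub[hb$k_rank > 2]))
  # rank exactly at the ceil boundary is a hub when the other criteria hold
  stats$gs_lung[2] <- 0.8
  hb2 <- hub_genes(stats, "lung")
  expect_true(hb2$is_hub[hb2$gene_id == "g02"])
})
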