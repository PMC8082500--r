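#' Configuration for the synthetic multi-tissue study
#'
#' Describes a two-condition, multi-tissue expression study with planted
#' structure: latent-factor co-expression modules elevated in a target
#' tissue, strictly tissue-specific genes, transcription factors with
#' condition-differential tissue profiles, miRNAs, and a planted regulatory
#' architecture containing known triad instances (including a
#' regulating-mutual "complex" with co-regulated targets). The defaults
#' emulate a 2-breed x 6-tissue x 3-replicate design at desk scale
#' (500 genes).
#'
#' @param n_genes Total number of genes (module + TF + TS + background).
#' @param tissues Tissue names (>= 2).
#' @param conditions Condition names (2).
#' @param replicates Replicates per (condition, tissue).
#' @param modules List of module specs `list(size =, tissue =)`; sizes must
#'   each be >= 3 and sum to less than `n_genes`.
#' @param cor_level Target within-module correlation of the latent-factor
#'   construction (default 0.9).
#' @param fold_change Elevation of a module's latent factor in its target
#'   tissue, in expression units (default 5). `fold_change = 0` removes the
#'   tissue effect.
#' @param n_tfs Number of transcription factors (>= 8 for the full default
#'   regulatory architecture; fewer disables the parts that do not fit).
#' @param n_mirnas Number of miRNAs.
#' @param n_ts_per_tissue Planted strictly tissue-specific genes per tissue.
#' @param ts_level,ts_noise_sd Expression level of a TS gene in its tissue
#'   and the sd of its noise.
#' @param tf_level Condition-specific TF expression in the focal (last)
#'   tissue, length-2 vector ordered as `conditions`.
#' @param tf_secondary Secondary-tissue elevation of each TF (keeps TF-TF
#'   correlations bounded so co-expression edges do not rewrite planted
#'   triads).
#' @param tf_noise_sd TF residual noise sd.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression
#'   parameters.
#' @param noise_sd Background gene noise sd.
#' @param tissue_sd,jitter_sd Between-tissue and per-sample sd of the module
#'   latent factors.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       tissues = c("muscle", "liver", "heart",
                                   "spleen", "kidney", "lung"),
                       conditions = c("highland", "lowland"),
                       replicates = 3,
                       modules = list(list(size = 60, tissue = "muscle"),
                                      list(size = 50, tissue = "spleen"),
                                      list(size = 45, tissue = "kidney"),
                                      list(size = 50, tissue = "lung")),
                       cor_level = 0.9,
                       fold_change = 5,
                       n_tfs = 8,
                       n_mirnas = 4,
                       n_ts_per_tissue = 4,
                       ts_level = 50, ts_noise_sd = 3,
                       tf_level = c(12, 4), tf_secondary = 6,
                       tf_noise_sd = 16,
                       baseline_meanlog = log(5), baseline_sdlog = 0.3,
                       noise_sd = 0.4,
                       tissue_sd = 0.5, jitter_sd = 0.5,
                       seed = 1) {
  stopifnot(length(tissues) >= 2, length(conditions) == 2, replicates >= 1)
  sizes <- vapply(modules, function(m) m$size, numeric(1))
  if (any(sizes < 3)) {
    stop("module size < 3: eigengene undefined", call. = FALSE)
  }
  n_ts <- n_ts_per_tissue * length(tissues)
  if (sum(sizes) + n_tfs + n_ts >= n_genes) {
    stop("module sizes + TFs + TS genes must leave room for background genes",
         call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, tissues = tissues, conditions = conditions,
    replicates = replicates, modules = modules, cor_level = cor_level,
    fold_change = fold_change, n_tfs = n_tfs, n_mirnas = n_mirnas,
    n_ts_per_tissue = n_ts_per_tissue, ts_level = ts_level,
    ts_noise_sd = ts_noise_sd, tf_level = tf_level,
    tf_secondary = tf_secondary, tf_noise_sd = tf_noise_sd,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    noise_sd = noise_sd, tissue_sd = tissue_sd, jitter_sd = jitter_sd,
    seed = seed
  ), class = "sim_config")
}

sim_gene_ids <- function(cfg) {
  sizes <- vapply(cfg$modules, function(m) m$size, numeric(1))
  n_mod <- sum(sizes)
  n_ts <- cfg$n_ts_per_tissue * length(cfg$tissues)
  n_bg <- cfg$n_genes - n_mod - cfg$n_tfs - n_ts
  list(
    module = paste0("g", formatC(seq_len(n_mod), width = 4, flag = "0")),
    tf = paste0("tf", seq_len(cfg$n_tfs)),
    ts = paste0("ts", formatC(seq_len(n_ts), width = 3, flag = "0")),
    background = paste0("b", formatC(seq_len(n_bg), width = 4, flag = "0")),
    mirna = if (cfg$n_mirnas > 0) paste0("mir", seq_len(cfg$n_mirnas))
            else character(0)
  )
}

#' Simulate a multi-tissue expression study with planted structure
#'
#' Module genes follow a latent-factor model: each module has one latent
#' per-sample factor (a per-tissue base level, elevated by `fold_change` in
#' the module's target tissue, plus per-sample jitter), and each member gene
#' is `baseline + loading x factor + noise` with the noise sd chosen so the
#' expected within-module correlation equals `cor_level` — exactly the
#' correlation structure weighted co-expression module detection assumes.
#' TS genes are expressed at `ts_level` in one tissue and near zero
#' elsewhere; TFs are elevated in the focal (last) tissue with a
#' condition-dependent level (so they carry differential-expression signal)
#' plus an individual secondary tissue; background genes are independent
#' noise around a log-normal baseline. All values are floored at 0 to
#' respect non-negativity.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expr` (an `expr_set`) and `truth`, a list holding
#'   the planted module assignment (`modules` tibble: gene_id, module,
#'   tissue), `ts_genes` (gene_id, tissue), `tf_ids`, `mirna_ids`, and the
#'   per-module latent `factors` (samples x modules matrix).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sim_gene_ids(cfg)
  md <- tidyr::expand_grid(condition = cfg$conditions,
                           tissue = cfg$tissues,
                           replicate = seq_len(cfg$replicates))
  md$sample_id <- paste(substr(md$condition, 1, 1), md$tissue, md$replicate,
                        sep = "_")
  md <- md[, c("sample_id", "condition", "tissue", "replicate")]
  n_s <- nrow(md)
  all_genes <- c(ids$module, ids$tf, ids$ts, ids$background)
  vals <- matrix(0, length(all_genes), n_s,
                 dimnames = list(all_genes, md$sample_id))

  # module genes: latent factor per module
  sizes <- vapply(cfg$modules, function(m) m$size, numeric(1))
  mod_label <- paste0("P", seq_along(cfg$modules))
  mod_tbl <- tibble::tibble(
    gene_id = ids$module,
    module = rep(mod_label, sizes),
    tissue = rep(vapply(cfg$modules, function(m) m$tissue, character(1)),
                 sizes)
  )
  factors <- matrix(0, n_s, length(cfg$modules),
                    dimnames = list(md$sample_id, mod_label))
  offset <- 0
  for (mi in seq_along(cfg$modules)) {
    spec <- cfg$modules[[mi]]
    base_t <- stats::rnorm(length(cfg$tissues), 0, cfg$tissue_sd)
    names(base_t) <- cfg$tissues
    f <- base_t[md$tissue] + cfg$fold_change * (md$tissue == spec$tissue) +
      stats::rnorm(n_s, 0, cfg$jitter_sd)
    factors[, mi] <- f
    var_f <- stats::var(f)
    gene_noise <- if (cfg$cor_level >= 1) 0 else
      sqrt(var_f * (1 - cfg$cor_level) / cfg$cor_level)
    for (g in seq_len(spec$size)) {
      loading <- stats::runif(1, 0.9, 1.1)
      base <- stats::rlnorm(1, cfg$baseline_meanlog, cfg$baseline_sdlog)
      vals[offset + g, ] <- base + loading * f +
        stats::rnorm(n_s, 0, gene_noise)
    }
    offset <- offset + spec$size
  }

  # transcription factors: focal-tissue elevation, condition-differential
  focal <- cfg$tissues[length(cfg$tissues)]
  tf_lv <- stats::setNames(cfg$tf_level, cfg$conditions)
  for (k in seq_len(cfg$n_tfs)) {
    secondary <- cfg$tissues[1 + (k - 1) %% (length(cfg$tissues) - 1)]
    vals[ids$tf[k], ] <- 15 +
      tf_lv[md$condition] * (md$tissue == focal) +
      cfg$tf_secondary * (md$tissue == secondary) +
      stats::rnorm(n_s, 0, cfg$tf_noise_sd)
  }

  # strictly tissue-specific genes; planted by preference in tissues that
  # carry no module so individual specificity is not confounded with
  # module co-expression
  mod_tissues <- vapply(cfg$modules, function(m) m$tissue, character(1))
  free_tissues <- setdiff(cfg$tissues, mod_tissues)
  if (!length(free_tissues)) free_tissues <- cfg$tissues
  ts_tbl <- tibble::tibble(
    gene_id = ids$ts,
    tissue = rep(free_tissues, length.out = length(ids$ts))
  )
  for (i in seq_len(nrow(ts_tbl))) {
    vals[ts_tbl$gene_id[i], ] <- 2 +
      cfg$ts_level * (md$tissue == ts_tbl$tissue[i]) +
      stats::rnorm(n_s, 0, cfg$ts_noise_sd)
  }

  # background: independent noise around a log-normal baseline
  for (g in ids$background) {
    base <- stats::rlnorm(1, cfg$baseline_meanlog, cfg$baseline_sdlog)
    vals[g, ] <- base + stats::rnorm(n_s, 0, cfg$noise_sd)
  }

  vals <- pmax(vals, 0)
  list(
    expr = expression_set(vals, md),
    truth = list(modules = mod_tbl, ts_genes = ts_tbl, tf_ids = ids$tf,
                 mirna_ids = ids$mirna, factors = factors, config = cfg)
  )
}

#' Planted regulatory arcs and triad instances
#'
#' Lays down a deterministic regulatory architecture on the simulated gene
#' set, written so its planted triads keep their class in the assembled
#' mixed network: a regulating-mutual "complex" (a mutual TF pair, tf1-tf2,
#' regulating a shared TF target tf3 and several co-regulated target genes
#' from the focal-tissue module), feed-forward loops through tf3 and tf4,
#' a regulated-mutual instance whose target pair is co-expressed (two
#' focal-module genes sharing tf5), a three-TF clique (tf6, tf7, tf8, all
#' mutual), and miRNA arcs. The TF pair of the complex is the only mutually
#' connected regulator pair sharing targets, so class-10 instances in the
#' assembled network are exactly the planted ones.
#'
#' @param cfg A [sim_config()] (needs `n_tfs >= 8` and at least 8 genes in
#'   the focal-tissue module for the full architecture; smaller settings
#'   plant what fits).
#' @return A list with `arcs` (tibble: from, to, type in tf/mirna, mutual
#'   flag) and `triads` (tibble: class_id, a, b, c) naming each planted
#'   triad instance with its class.
#' @export
simulate_regulatory_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_gene_ids(cfg)
  focal <- cfg$tissues[length(cfg$tissues)]
  sizes <- vapply(cfg$modules, function(m) m$size, numeric(1))
  tissues_of <- vapply(cfg$modules, function(m) m$tissue, character(1))
  focal_mod <- which(tissues_of == focal)[1]
  focal_genes <- if (is.na(focal_mod)) character(0) else
    ids$module[(cumsum(sizes)[focal_mod] - sizes[focal_mod] + 1):
                 cumsum(sizes)[focal_mod]]
  arc <- function(from, to, type, mutual = FALSE) {
    tibble::tibble(from = from, to = to, type = type, mutual = mutual)
  }
  arcs <- list()
  triads <- list()
  tf <- ids$tf
  if (cfg$n_tfs >= 5 && length(focal_genes) >= 8) {
    targets <- focal_genes[1:6]
    # the complex: mutual tf1-tf2 pair regulating tf3 and six module targets
    arcs <- c(arcs, list(
      arc(tf[1], tf[2], "tf", TRUE), arc(tf[2], tf[1], "tf", TRUE),
      arc(tf[1], tf[3], "tf"), arc(tf[2], tf[3], "tf"),
      arc(tf[1], targets, "tf"), arc(tf[2], targets, "tf"),
      # tf3 regulates two of the shared targets (closing FFLs) plus its
      # own downstream program, so the shared TF target is a high-degree
      # regulator like its real counterparts
      arc(tf[3], targets[1:2], "tf"),
      arc(tf[3], focal_genes[seq(15, min(26, length(focal_genes)))], "tf"),
      # an FFL through tf4
      arc(tf[1], tf[4], "tf"), arc(tf[4], targets[1], "tf"),
      # regulated mutual: tf5 targets a co-expressed module pair
      arc(tf[5], focal_genes[7:8], "tf")
    ))
    triads <- c(triads, list(
      tibble::tibble(class_id = 10, a = tf[1], b = tf[2],
                     c = c(tf[3], targets)),
      tibble::tibble(class_id = 7,
                     a = c(tf[1], tf[1], tf[2], tf[2], tf[1]),
                     b = c(tf[3], tf[3], tf[3], tf[3], tf[4]),
                     c = c(targets[1:2], targets[1:2], targets[1])),
      tibble::tibble(class_id = 9, a = tf[5], b = focal_genes[7],
                     c = focal_genes[8])
    ))
  }
  if (cfg$n_tfs >= 8) {
    pairs <- utils::combn(tf[6:8], 2)
    for (i in seq_len(ncol(pairs))) {
      arcs <- c(arcs, list(arc(pairs[1, i], pairs[2, i], "tf", TRUE),
                           arc(pairs[2, i], pairs[1, i], "tf", TRUE)))
    }
    triads <- c(triads, list(
      tibble::tibble(class_id = 13, a = tf[6], b = tf[7], c = tf[8])))
  }
  if (cfg$n_mirnas > 0) {
    n_bg <- length(ids$background)
    for (j in seq_len(cfg$n_mirnas)) {
      tg <- if (length(focal_genes) >= 10 + j) {
        focal_genes[10 + j]
      } else {
        ids$background[min(n_bg, j)]
      }
      arcs <- c(arcs, list(arc(ids$mirna[j], tg, "mirna")))
    }
  }
  arcs <- if (length(arcs)) dplyr::distinct(dplyr::bind_rows(arcs)) else
    tibble::tibble(from = character(0), to = character(0),
                   type = character(0), mutual = logical(0))
  triads <- if (length(triads)) dplyr::bind_rows(triads) else
    tibble::tibble(class_id = integer(0), a = character(0),
                   b = character(0), c = character(0))
  list(arcs = arcs, triads = triads)
}

#' Simulate JASPAR-style PWMs and promoter sequences with planted sites
#'
#' For each TF with planted targets, draws a 10-bp consensus and a count
#' matrix dominated by it, then writes the consensus into the promoter of
#' every planted target at a random position; all other promoter sequence is
#' i.i.d. uniform background. Scanning the promoters with the matching PWM
#' at a high relative-score threshold therefore recovers exactly the planted
#' arcs (a planted consensus site scores relScore 1 by construction).
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_regulatory_truth()].
#' @param promoter_length Promoter length in bp (default 500).
#' @param motif_length Consensus length (default 10; length >= 10 keeps the
#'   expected number of background hits per promoter well below 1 at a 0.99
#'   threshold).
#' @return List with `pwms` (a list of [pwm()] objects, one per planted TF)
#'   and `promoters` (named character vector of A/C/G/T sequences covering
#'   every gene that is a target of any planted TF arc).
#' @export
simulate_pwm_promoters <- function(cfg, truth, promoter_length = 500,
                                   motif_length = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  bases <- c("A", "C", "G", "T")
  tf_arcs <- truth$arcs[truth$arcs$type == "tf" & !truth$arcs$mutual, ]
  tfs <- unique(tf_arcs$from)
  pwms <- list()
  consensus <- list()
  for (t in tfs) {
    cons <- sample(bases, motif_length, replace = TRUE)
    counts <- matrix(5, 4, motif_length, dimnames = list(bases, NULL))
    counts[cbind(match(cons, bases), seq_len(motif_length))] <- 85
    pwms[[t]] <- pwm(t, counts)
    consensus[[t]] <- paste(cons, collapse = "")
  }
  genes <- unique(tf_arcs$to)
  promoters <- vapply(genes, function(g) {
    paste(sample(bases, promoter_length, replace = TRUE), collapse = "")
  }, character(1))
  occupied <- stats::setNames(vector("list", length(genes)), genes)
  for (i in seq_len(nrow(tf_arcs))) {
    g <- tf_arcs$to[i]
    site <- consensus[[tf_arcs$from[i]]]
    # non-overlapping placement so one planted site never clobbers another
    for (try in 1:200) {
      pos <- sample.int(promoter_length - motif_length + 1, 1)
      span <- pos:(pos + motif_length - 1)
      if (!any(span %in% occupied[[g]])) break
    }
    occupied[[g]] <- c(occupied[[g]], span)
    substr(promoters[g], pos, pos + motif_length - 1) <- site
  }
  list(pwms = pwms, promoters = promoters)
}

#' Simulate miRNA target records around the filtering cutoffs
#'
#' Planted miRNA arcs get alignment scores and duplex energies that pass the
#' downstream filter (total score >= 140, total energy <= -20 kcal/mol);
#' decoy records are added on each side of each boundary so the filter is
#' exercised.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_regulatory_truth()].
#' @return Tibble (mirna_id, gene_id, tot_score, tot_energy) with attribute
#'   `planted` marking the true arcs.
#' @export
simulate_mirna_records <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  mir_arcs <- truth$arcs[truth$arcs$type == "mirna", ]
  ids <- sim_gene_ids(cfg)
  real <- tibble::tibble(
    mirna_id = mir_arcs$from, gene_id = mir_arcs$to,
    tot_score = stats::runif(nrow(mir_arcs), 150, 180),
    tot_energy = stats::runif(nrow(mir_arcs), -30, -22)
  )
  n_decoy <- max(2, nrow(real))
  decoy_genes <- sample(ids$background, n_decoy, replace = TRUE)
  decoys <- tibble::tibble(
    mirna_id = sample(c(ids$mirna, "mir_decoy"), n_decoy, replace = TRUE),
    gene_id = decoy_genes,
    tot_score = stats::runif(n_decoy, 100, 139.5),
    tot_energy = stats::runif(n_decoy, -19.5, -10)
  )
  out <- dplyr::bind_rows(real, decoys)
  attr(out, "planted") <- real
  out
}

#' Run the whole generator: expression, truth, PWMs, promoters, miRNA records
#'
#' @param cfg A [sim_config()].
#' @return List with `expr`, `truth` (including `arcs` and `triads`),
#'   `pwms`, `promoters` and `mirna_records`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  sim <- simulate_expression(cfg)
  reg <- simulate_regulatory_truth(cfg)
  sim$truth$arcs <- reg$arcs
  sim$truth$triads <- reg$triads
  pp <- simulate_pwm_promoters(cfg, reg)
  list(expr = sim$expr, truth = sim$truth, pwms = pp$pwms,
       promoters = pp$promoters,
       mirna_records = simulate_mirna_records(cfg, reg))
}
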