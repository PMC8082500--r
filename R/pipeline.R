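#' Pipeline configuration
#'
#' Collects every stage parameter and input of the end-to-end analysis.
#' Inputs may be given as paths (TSV/JASPAR/FASTA, read at stage start) or
#' as in-memory objects; all seeds and thresholds are recorded in the run
#' manifest for auditability.
#'
#' @param expr Expression input: path to a TSV or an `expr_set`.
#' @param meta Metadata TSV path (ignored when `expr` is an `expr_set`).
#' @param outdir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param keep_fraction MAD filter fraction.
#' @param beta Soft power; `NULL` selects it from `powers` by the
#'   scale-free fit criterion.
#' @param powers,r2_goal Soft-threshold selection grid and goal.
#' @param min_size,cut_height Module detection parameters.
#' @param merge_cor Module-merge eigengene correlation threshold.
#' @param condition Focal condition (default: first in the metadata).
#' @param focal_tissue Focal tissue for GS/hub/score stages (default: last
#'   tissue in the metadata).
#' @param clusters,fuzzifier Fuzzy c-means parameters.
#' @param tf_ids,tf_arcs,pwms,promoters Regulatory inputs: TF id vector;
#'   either a precomputed arc table (tibble or TSV path with from/to) or
#'   PWMs (list or JASPAR path) plus promoters (named vector or FASTA
#'   path) to scan.
#' @param rel_score PWM scan threshold.
#' @param mirna_ids,mirna_records miRNA id vector and target records
#'   (tibble or path).
#' @param score_min,energy_max miRNA target filter cutoffs.
#' @param coexpr_cutoff Adjacency cutoff for co-expression edges.
#' @param n_random,switches_per_arc Null-ensemble parameters for the motif
#'   stage.
#' @param weights A [score_weights()].
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr, meta = NULL, outdir = NULL,
                            keep_fraction = 0.5, beta = 6, powers = 1:20,
                            r2_goal = 0.85, min_size = 30, cut_height = 0.95,
                            merge_cor = 0.9, condition = NULL,
                            focal_tissue = NULL, clusters = 8,
                            fuzzifier = 2, tf_ids = character(0),
                            tf_arcs = NULL, pwms = NULL, promoters = NULL,
                            rel_score = 0.85, mirna_ids = character(0),
                            mirna_records = NULL, score_min = 140,
                            energy_max = -20, coexpr_cutoff = 0.1,
                            n_random = 200, switches_per_arc = 20,
                            weights = score_weights(), seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_input <- function(value, reader, what) {
  if (is.null(value)) return(NULL)
  if (is.character(value) && length(value) == 1) {
    if (!file.exists(value)) {
      stop("input file for '", what, "' does not exist: ", value,
           call. = FALSE)
    }
    return(reader(value))
  }
  value
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — filter, network construction
#' and module detection, module statistics and key-module/hub calls,
#' expression patterns and tissue specificity, regulatory-network assembly,
#' triad census and significance, importance scoring and top-complex
#' extraction — writing each stage's table to `outdir` along with a JSON
#' manifest recording every parameter and seed. A failing stage aborts with
#' the stage name; artifacts already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results (invisibly includes the manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (!is.null(cfg$outdir) &&
      !dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  emit <- function(tbl, file) {
    if (!is.null(cfg$outdir)) {
      readr::write_tsv(tbl, file.path(cfg$outdir, file))
    }
  }
  res <- list()

  es <- run_stage("read", {
    if (inherits(cfg$expr, "expr_set")) cfg$expr else {
      if (is.null(cfg$meta)) stop("config field 'meta' is missing")
      read_expression(cfg$expr, cfg$meta)
    }
  })
  md <- es$metadata
  condition <- cfg$condition %||% unique(md$condition)[1]
  focal <- cfg$focal_tissue %||% utils::tail(unique(md$tissue), 1)

  res$filtered <- run_stage("filter", mad_filter(es, cfg$keep_fraction))
  emit(filter_report(res$filtered)$mad, "filter_report.tsv")

  beta <- cfg$beta
  if (is.null(beta)) {
    res$soft_threshold <- run_stage("soft_threshold",
      pick_soft_threshold(res$filtered, cfg$powers, cfg$r2_goal))
    beta <- res$soft_threshold$beta
    emit(tidy(res$soft_threshold), "soft_threshold.tsv")
  }

  res$adjacency <- run_stage("adjacency",
    adjacency_matrix(res$filtered, beta))
  res$modules <- run_stage("modules", {
    tom <- tom_similarity(res$adjacency)
    mm <- detect_modules(tom, cfg$min_size, cfg$cut_height)
    merge_close_modules(res$filtered, mm, cfg$merge_cor)
  })
  emit(res$modules, "modules.tsv")

  res$eigengenes <- run_stage("eigengenes",
    module_eigengenes(res$filtered, res$modules))
  res$stats <- run_stage("module_stats",
    module_stats(res$filtered, res$modules, res$adjacency,
                 condition = condition))
  emit(res$stats, "module_stats.tsv")

  res$key_modules <- run_stage("key_modules",
    key_modules(res$eigengenes, res$filtered, res$stats,
                condition = condition))
  emit(res$key_modules, "key_modules.tsv")

  res$concepts <- run_stage("network_concepts", {
    keys <- res$key_modules[res$key_modules$is_key, ]
    purrr::pmap_dfr(keys[, c("module", "tissue")], function(module, tissue) {
      genes <- res$modules$gene_id[res$modules$module == module]
      dplyr::bind_cols(tibble::tibble(module = module, tissue = tissue),
                       network_concepts(res$adjacency[genes, genes]))
    })
  })
  emit(res$concepts, "network_concepts.tsv")

  res$hubs <- run_stage("hubs", {
    keys <- res$key_modules[res$key_modules$is_key, c("module", "tissue")]
    if (nrow(keys)) hub_genes(res$stats, keys) else
      hub_genes(res$stats, focal)
  })
  emit(res$hubs, "hub_genes.tsv")

  res$profile <- run_stage("tissue_means",
    tissue_means(res$filtered, condition))
  res$tsi <- run_stage("tsi", tsi(res$profile))
  emit(res$tsi, "tsi.tsv")

  res$patterns <- run_stage("patterns", {
    focal_mod <- res$key_modules$module[res$key_modules$is_key &
                                          res$key_modules$tissue == focal]
    genes <- if (length(focal_mod)) {
      res$modules$gene_id[res$modules$module %in% focal_mod]
    } else res$modules$gene_id[res$modules$module != "unassigned"]
    prof <- res$profile[res$profile$gene_id %in% genes, ]
    fuzzy_cmeans(standardize_profile(prof),
                 centers = min(cfg$clusters, max(2, length(genes) - 1)),
                 m = cfg$fuzzifier, seed = cfg$seed)
  })
  emit(tidy(res$patterns), "pattern_membership.tsv")

  tf_arcs <- run_stage("tf_arcs", {
    given <- resolve_input(cfg$tf_arcs, function(p)
      readr::read_tsv(p, show_col_types = FALSE), "tf_arcs")
    if (!is.null(given)) given else {
      pwms <- resolve_input(cfg$pwms, read_jaspar, "pwms")
      promoters <- resolve_input(cfg$promoters, read_promoters, "promoters")
      if (is.null(pwms) || is.null(promoters)) NULL else {
        hits <- pwm_scan(pwms, promoters, cfg$rel_score)
        dplyr::distinct(tibble::tibble(from = hits$tf_id, to = hits$gene_id,
                                       rel_score = hits$rel_score))
      }
    }
  })
  mirna_arcs <- run_stage("mirna_arcs", {
    rec <- resolve_input(cfg$mirna_records, read_mirna_targets,
                         "mirna_records")
    if (is.null(rec)) NULL else {
      keep <- filter_mirna_targets(rec, cfg$score_min, cfg$energy_max)
      tibble::tibble(from = keep$mirna_id, to = keep$gene_id)
    }
  })

  res$network <- run_stage("grn", {
    assigned <- res$modules[res$modules$module != "unassigned", ]
    assemble_network(assigned, tf_arcs = tf_arcs, mirna_arcs = mirna_arcs,
                     a = res$adjacency, coexpr_cutoff = cfg$coexpr_cutoff,
                     tfs = cfg$tf_ids, mirnas = cfg$mirna_ids,
                     hubs = res$hubs$gene_id[res$hubs$is_hub])
  })
  if (!is.null(cfg$outdir)) {
    write_network(res$network, file.path(cfg$outdir, "network_edges.tsv"),
                  file.path(cfg$outdir, "network_nodes.tsv"))
  }

  res$significance <- run_stage("motifs",
    triad_significance(res$network, n_random = cfg$n_random,
                       switches_per_arc = cfg$switches_per_arc,
                       seed = cfg$seed))
  emit(tidy(res$significance), "triad_significance.tsv")

  res$scores <- run_stage("scores", {
    ns <- node_scores(res$network, res$filtered, focal, res$tsi,
                      cfg$weights)
    esg <- edge_scores(res$network, res$adjacency)
    cen <- triad_census(res$network, instances = TRUE)
    inst <- dplyr::bind_rows(lapply(c(7, 9, 10), function(k)
      find_motif_instances(res$network, k, census = cen)))
    ms <- motif_scores(res$network, inst, ns, esg, cfg$weights$alpha)
    list(nodes = ns, edges = esg, motifs = ms,
         top = rank_top_nodes(ns, res$network),
         complex = if (any(inst$class_id == 10))
           extract_top_complex(res$network, ms) else NULL)
  })
  emit(res$scores$nodes, "node_scores.tsv")
  emit(res$scores$motifs, "motif_scores.tsv")
  emit(res$scores$top, "top_nodes.tsv")

  manifest <- list(
    parameters = list(
      keep_fraction = cfg$keep_fraction, beta = beta,
      min_size = cfg$min_size, cut_height = cfg$cut_height,
      merge_cor = cfg$merge_cor, condition = condition,
      focal_tissue = focal, clusters = cfg$clusters,
      fuzzifier = cfg$fuzzifier, rel_score = cfg$rel_score,
      score_min = cfg$score_min, energy_max = cfg$energy_max,
      coexpr_cutoff = cfg$coexpr_cutoff, n_random = cfg$n_random,
      switches_per_arc = cfg$switches_per_arc
    ),
    seeds = list(master = cfg$seed, patterns = cfg$seed,
                 motifs = cfg$seed),
    outputs = if (is.null(cfg$outdir)) character(0) else
      list.files(cfg$outdir)
  )
  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  invisible(res)
}

#' One-command synthetic end-to-end demo
#'
#' Simulates a complete study ([simulate_study()]), writes its fixtures
#' (expression and metadata TSV, planted-arc TSV, JASPAR PWMs, promoter
#' FASTA, miRNA records) and runs the full pipeline on them.
#'
#' @param outdir Output directory (default: a fresh temporary directory).
#' @param seed Master seed.
#' @param n_random Null-ensemble size for the motif stage (kept modest for
#'   a demo).
#' @return The [run_pipeline()] result, with the simulation truth attached
#'   as `truth`.
#' @export
demo_pipeline <- function(outdir = tempfile("triadnet_demo"), seed = 1,
                          n_random = 200) {
  sim <- simulate_study(sim_config(seed = seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "metadata.tsv"))
  readr::write_tsv(sim$truth$arcs, file.path(outdir, "planted_arcs.tsv"))
  write_jaspar(sim$pwms, file.path(outdir, "pwms.jaspar"))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    write_promoters(sim$promoters, file.path(outdir, "promoters.fa"))
  }
  readr::write_tsv(sim$mirna_records, file.path(outdir, "mirna_targets.tsv"))
  tf_truth <- sim$truth$arcs[sim$truth$arcs$type == "tf", c("from", "to")]
  cfg <- pipeline_config(
    expr = file.path(outdir, "expression.tsv"),
    meta = file.path(outdir, "metadata.tsv"),
    outdir = outdir,
    tf_arcs = tf_truth,
    tf_ids = sim$truth$tf_ids,
    mirna_ids = sim$truth$mirna_ids,
    mirna_records = sim$mirna_records,
    n_random = n_random,
    seed = seed
  )
  res <- run_pipeline(cfg)
  res$truth <- sim$truth
  invisible(res)
}
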