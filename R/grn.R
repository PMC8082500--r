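#' Position weight matrix for a transcription factor
#'
#' Wraps a 4 x L count (or probability) matrix with rows A, C, G, T. Columns
#' are normalized to probabilities, a pseudocount is added and the columns
#' renormalized, and the log-odds matrix against the background is
#' precomputed together with its attainable per-column extremes — the basis
#' of the relative score used in scanning.
#'
#' @param tf_id Identifier of the factor.
#' @param counts 4 x L numeric matrix (rownames A, C, G, T, or rows in that
#'   order), L >= 4.
#' @param pseudocount Probability added to every cell after normalization
#'   (default 0.01); keeps all log-odds finite.
#' @param background Background base frequencies (A, C, G, T), default
#'   uniform.
#' @return Object of class `pwm` with elements `tf_id`, `prob`,
#'   `log_odds`, `score_min`, `score_max`, `length`.
#' @export
pwm <- function(tf_id, counts, pseudocount = 0.01,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM needs 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(counts) < 2) stop("PWM length must be >= 2", call. = FALSE)
  if (any(counts < 0)) stop("PWM entries must be non-negative", call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  p <- sweep(counts, 2, colSums(counts), "/")
  p <- p + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  lo <- log2(p / background)
  structure(list(tf_id = tf_id, counts = counts, prob = p, log_odds = lo,
                 score_min = sum(apply(lo, 2, min)),
                 score_max = sum(apply(lo, 2, max)),
                 length = ncol(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
  cat("<pwm> ", x$tf_id, ", length ", x$length, ", consensus ", cons, "\n",
      sep = "")
  invisible(x)
}

#' Read and write PWMs in JASPAR format
#'
#' The JASPAR flat format: a `>identifier name` header line followed by four
#' rows `A [ 1 2 3 ]` (brackets optional). [write_jaspar()] is the inverse.
#'
#' @param path File path.
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in '", path, "'", call. = FALSE)
  pwms <- list()
  for (h in heads) {
    fields <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    id <- if (length(fields) >= 2) fields[2] else fields[1]
    rows <- lines[(h + 1):(h + 4)]
    counts <- do.call(rbind, lapply(rows, function(r) {
      nums <- gsub("[][A-Za-z]", " ", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }))
    pwms[[id]] <- pwm(id, counts)
  }
  pwms
}

#' @rdname read_jaspar
#' @param pwms Named list of [pwm()] objects; the stored count matrices are
#'   written, so a write/read round trip reproduces the PWMs.
#' @export
write_jaspar <- function(pwms, path) {
  out <- unlist(lapply(pwms, function(p) {
    m <- round(p$counts, 4)
    c(paste0(">", p$tf_id, " ", p$tf_id),
      vapply(1:4, function(i) {
        paste0(rownames(m)[i], "  [ ", paste(m[i, ], collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(out, path)
  invisible(pwms)
}

#' Read promoter sequences from a FASTA file
#'
#' Record ids are gene ids; sequences must be over A/C/G/T/N.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_promoters
#' @param promoters Named character vector of sequences.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  names(ss) <- names(promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(promoters)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(seq, NULL),
                                  function(ch) paste(rev(ch), collapse = ""),
                                  character(1)))
}

scan_one_strand <- function(p, seq) {
  n <- nchar(seq)
  L <- p$length
  if (n < L) return(numeric(0))
  code <- match(strsplit(seq, NULL)[[1]], c("A", "C", "G", "T"))
  starts <- seq_len(n - L + 1)
  idx <- outer(starts, 0:(L - 1), "+")
  codes <- matrix(code[idx], nrow = length(starts))
  has_n <- rowSums(is.na(codes)) > 0
  scores <- rep(NA_real_, length(starts))
  ok <- !has_n
  if (any(ok)) {
    cols <- matrix(rep(seq_len(L), each = sum(ok)), ncol = L)
    scores[ok] <- rowSums(matrix(p$log_odds[cbind(as.vector(codes[ok, ,
                                                                  drop = FALSE]),
                                                  as.vector(cols))],
                                 nrow = sum(ok)))
  }
  scores
}

#' Scan promoters with PWMs at a relative-score threshold
#'
#' Every window on both strands is scored by the PWM log-odds sum and
#' converted to a relative score,
#' `relScore = (s - s_min) / (s_max - s_min)`, where `s_min`/`s_max` are the
#' PWM's attainable extremes — so the consensus scores exactly 1 and the
#' anti-consensus exactly 0 regardless of PWM scale. Windows containing N
#' are skipped; hits at or above `threshold` are returned. Positions are
#' 0-based on the forward (promoter) strand.
#'
#' @param pwms A [pwm()] or (named) list of them.
#' @param promoters Named character vector of promoter sequences (names =
#'   gene ids) over A/C/G/T/N.
#' @param threshold Minimum relScore, inclusive (default 0.85, the
#'   pipeline's operating point).
#' @return Tibble (tf_id, gene_id, position, strand, rel_score), sorted.
#' @export
pwm_scan <- function(pwms, promoters, threshold = 0.85) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bad <- grepl("[^ACGTN]", toupper(promoters))
  if (any(bad)) {
    stop("sequence '", names(promoters)[bad][1],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  }
  promoters <- toupper(promoters)
  res <- list()
  for (p in pwms) {
    denom <- p$score_max - p$score_min
    for (g in names(promoters)) {
      seq <- promoters[[g]]
      if (nchar(seq) < p$length) {
        warning("sequence '", g, "' shorter than PWM '", p$tf_id, "'",
                call. = FALSE)
        next
      }
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else revcomp(seq)
        sc <- scan_one_strand(p, s)
        rel <- (sc - p$score_min) / denom
        hit <- which(!is.na(rel) & rel >= threshold)
        if (!length(hit)) next
        pos0 <- if (strand == "+") hit - 1 else
          nchar(seq) - hit - p$length + 1
        res[[length(res) + 1]] <- tibble::tibble(
          tf_id = p$tf_id, gene_id = g, position = pos0,
          strand = strand, rel_score = rel[hit])
      }
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(tf_id = character(0), gene_id = character(0),
                   position = integer(0), strand = character(0),
                   rel_score = numeric(0))
  dplyr::arrange(out, .data$tf_id, .data$gene_id, .data$position,
                 .data$strand)
}

#' Read miRNA target records
#'
#' Accepts either a 4-column TSV (mirna_id, gene_id, tot_score, tot_energy)
#' or the plain-text summary dialect of lines
#' `>mirna gene tot_score tot_energy`.
#'
#' @param path File path.
#' @return Tibble (mirna_id, gene_id, tot_score, tot_energy).
#' @export
read_mirna_targets <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    lines <- grep("^>", readLines(path), value = TRUE)
    parts <- strsplit(sub("^>\\s*", "", lines), "\\s+")
    tibble::tibble(
      mirna_id = vapply(parts, `[`, "", 1),
      gene_id = vapply(parts, `[`, "", 2),
      tot_score = as.numeric(vapply(parts, `[`, "", 3)),
      tot_energy = as.numeric(vapply(parts, `[`, "", 4))
    )
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = "ccdd")
  }
}

#' Filter miRNA target records at the score/energy cutoffs
#'
#' Keeps records with alignment score at least `score_min` and duplex
#' energy at most `energy_max` (both inclusive) — the standard operating
#' point is 140 and -20 kcal/mol.
#'
#' @param records Tibble (mirna_id, gene_id, tot_score, tot_energy).
#' @param score_min Minimum total score (default 140).
#' @param energy_max Maximum total energy in kcal/mol (default -20).
#' @return Filtered tibble.
#' @export
filter_mirna_targets <- function(records, score_min = 140,
                                 energy_max = -20) {
  dplyr::filter(records, .data$tot_score >= score_min,
                .data$tot_energy <= energy_max)
}

#' Assemble the mixed gene regulatory network
#'
#' Combines directed regulation arcs (TF -> target from PWM scanning or
#' planted truth; miRNA -> target from filtered records) with undirected
#' co-expression edges (adjacency at or above `coexpr_cutoff`) among module
#' genes. Nodes carry TF/miRNA/hub flags and module labels; isolated nodes
#' are dropped. Self-arcs are rejected and duplicate typed edges collapsed,
#' so the edge multiset is byte-for-byte reproducible from identical
#' inputs.
#'
#' @param module_genes Tibble (gene_id, module) of the co-expression side's
#'   gene universe, or a character vector of gene ids.
#' @param tf_arcs Tibble with columns `from`, `to` (TF regulation); extra
#'   columns are kept as arc metadata after deduplication (best
#'   `rel_score` retained per pair when present).
#' @param mirna_arcs Tibble with columns `from`, `to` (or `mirna_id`,
#'   `gene_id`).
#' @param a Adjacency matrix over (at least) the module genes; `NULL`
#'   disables co-expression edges.
#' @param coexpr_cutoff Minimum adjacency for a co-expression edge
#'   (default 0.1; inclusive). The choice of which co-expressed pairs enter
#'   the network is a reporting convention, and edge counts are sensitive
#'   to it — expose and record it.
#' @param tfs Character vector of TF gene ids (arc sources must be TFs or
#'   miRNAs).
#' @param mirnas Character vector of miRNA ids.
#' @param hubs Character vector of hub gene ids (flag only).
#' @return Object of class `mixed_network`: list with `nodes`
#'   (tibble: node, is_tf, is_mirna, is_hub, module) and `edges` (tibble:
#'   from, to, type in tf_regulation/mirna_regulation/coexpression, weight,
#'   directed).
#' @export
assemble_network <- function(module_genes, tf_arcs = NULL, mirna_arcs = NULL,
                             a = NULL, coexpr_cutoff = 0.1,
                             tfs = character(0), mirnas = character(0),
                             hubs = character(0)) {
  if (is.character(module_genes)) {
    module_genes <- tibble::tibble(gene_id = module_genes,
                                   module = NA_character_)
  }
  module_genes <- tibble::as_tibble(module_genes)
  norm_arcs <- function(arcs, type) {
    if (is.null(arcs) || !nrow(arcs)) {
      return(tibble::tibble(from = character(0), to = character(0),
                            type = character(0), weight = numeric(0),
                            directed = logical(0)))
    }
    if ("mirna_id" %in% names(arcs)) {
      arcs <- dplyr::rename(arcs, from = "mirna_id", to = "gene_id")
    }
    if ("tf_id" %in% names(arcs)) {
      arcs <- dplyr::rename(arcs, from = "tf_id", to = "gene_id")
    }
    if (any(arcs$from == arcs$to)) {
      stop("self-arc on '", arcs$from[arcs$from == arcs$to][1], "'",
           call. = FALSE)
    }
    w <- if ("rel_score" %in% names(arcs)) arcs$rel_score else NA_real_
    out <- tibble::tibble(from = arcs$from, to = arcs$to, type = type,
                          weight = w, directed = TRUE)
    out <- dplyr::arrange(out, .data$from, .data$to,
                          dplyr::desc(.data$weight))
    dplyr::distinct(out, .data$from, .data$to, .keep_all = TRUE)
  }
  tf_e <- norm_arcs(tf_arcs, "tf_regulation")
  mir_e <- norm_arcs(mirna_arcs, "mirna_regulation")
  regulators <- union(tfs, mirnas)
  bad <- setdiff(unique(c(tf_e$from, mir_e$from)), regulators)
  if (length(bad)) {
    stop("arc source '", bad[1], "' is not flagged TF or miRNA",
         call. = FALSE)
  }
  universe <- union(module_genes$gene_id, union(tfs, mirnas))
  stray <- setdiff(c(tf_e$to, mir_e$to, mir_e$from, tf_e$from), universe)
  if (length(stray)) {
    warning(length(stray), " arc endpoint(s) outside the module gene / TF ",
            "/ miRNA universe dropped (e.g. '", stray[1], "')",
            call. = FALSE)
    tf_e <- tf_e[tf_e$from %in% universe & tf_e$to %in% universe, ]
    mir_e <- mir_e[mir_e$from %in% universe & mir_e$to %in% universe, ]
  }
  co_e <- tibble::tibble(from = character(0), to = character(0),
                         type = character(0), weight = numeric(0),
                         directed = logical(0))
  if (!is.null(a)) {
    genes <- intersect(module_genes$gene_id, rownames(a))
    sub <- a[genes, genes, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- -Inf
    hit <- which(sub >= coexpr_cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      co_e <- tibble::tibble(
        from = genes[hit[, 1]], to = genes[hit[, 2]], type = "coexpression",
        weight = sub[hit], directed = FALSE)
      co_e <- dplyr::arrange(co_e, .data$from, .data$to)
    }
  }
  edges <- dplyr::bind_rows(tf_e, mir_e, co_e)
  nodes_used <- unique(c(edges$from, edges$to))
  mod_of <- stats::setNames(module_genes$module, module_genes$gene_id)
  nodes <- tibble::tibble(
    node = sort(nodes_used),
    is_tf = sort(nodes_used) %in% tfs,
    is_mirna = sort(nodes_used) %in% mirnas,
    is_hub = sort(nodes_used) %in% hubs,
    module = unname(mod_of[sort(nodes_used)])
  )
  structure(list(nodes = nodes, edges = edges), class = "mixed_network")
}

#' @export
print.mixed_network <- function(x, ...) {
  cat("<mixed_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_tf), " TF, ", sum(x$nodes$is_mirna), " miRNA, ",
      sum(x$nodes$is_hub), " hub), ", nrow(x$edges), " edges (",
      sum(x$edges$directed), " regulation, ", sum(!x$edges$directed),
      " co-expression)\n", sep = "")
  invisible(x)
}

#' Node and edge tables of a mixed network
#' @param net A `mixed_network`.
#' @return A tibble.
#' @export
node_table <- function(net) net$nodes

#' @rdname node_table
#' @export
edge_table <- function(net) net$edges

#' Write a mixed network as edge-list and node-table TSVs
#' @param net A `mixed_network`.
#' @param edge_path,node_path Output paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edge_path, node_path) {
  readr::write_tsv(net$edges, edge_path)
  readr::write_tsv(net$nodes, node_path)
  invisible(net)
}
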