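#' Design of a synthetic multi-omic cohort
#'
#' Describes a two-class (tumor/normal) cohort with planted,
#' direction-consistent signal in three layers: negative-binomial expression
#' counts for genes and miRNAs, piecewise-constant log2 copy-ratio segment
#' profiles for tumor samples, and a multi-database miRNA-target table.
#' Planted "core" genes are simultaneously differentially expressed,
#' copy-number altered in the concordant direction, and consensus targets of
#' an oppositely deregulated miRNA; decoy genes altered in only one or two
#' layers populate every other region of the three-layer Venn diagram so
#' integration specificity is testable.  A planted master-regulator miRNA
#' targets a block of the co-expression network genes.
#'
#' Defaults are the strong-signal validation conditions: 40 vs 40 samples,
#' a log2 fold change of 2 at NB dispersion 0.1 for planted features,
#' copy-number amplitude 0.8 log2 units in 80% of tumor samples, and
#' 7-database votes for true target pairs against 2-vote noise pairs.
#'
#' @param n_tumor,n_normal Samples per class.
#' @param n_genes,n_mirnas Feature counts.
#' @param nb_dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param baseline_mean_range Range of per-feature baseline means
#'   (log-uniform draw).
#' @param planted_mean_range Baseline-mean range for planted features (kept
#'   high enough that the quantile filter retains them).
#' @param lfc_effect Log2 fold change applied to planted features.
#' @param n_core_up,n_core_down Planted core genes per direction.
#' @param n_decoys_per_layer Decoy genes per Venn region and direction.
#' @param cna_amplitude Log2-ratio magnitude of planted segments.
#' @param cna_sample_fraction Fraction of tumor samples carrying each
#'   planted alteration.
#' @param cna_noise_sd SD of background segment means.
#' @param markers_per_segment_range Integer range for marker counts.
#' @param target_vote_signal Database votes for true regulatory pairs
#'   (0..10).
#' @param target_vote_noise Votes for spurious pairs.
#' @param n_up_mirnas,n_down_mirnas Deregulated miRNAs per direction.
#' @param master_mirna_n_targets Network genes targeted by the planted
#'   master miRNA.
#' @param n_network_genes Size of the synthetic co-expression network.
#' @param n_overlap_genes Core genes carried by "published" signature files.
#' @param lib_size_factors Optional per-sample library-size multipliers
#'   (length n_tumor + n_normal); default NULL means equal libraries.
#' @param rng_seed Integer seed.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_tumor = 40L, n_normal = 40L,
                              n_genes = 3000L, n_mirnas = 150L,
                              nb_dispersion = 0.1,
                              baseline_mean_range = c(20, 200),
                              planted_mean_range = c(80, 200),
                              lfc_effect = 2,
                              n_core_up = 10L, n_core_down = 10L,
                              n_decoys_per_layer = 4L,
                              cna_amplitude = 0.8,
                              cna_sample_fraction = 0.8,
                              cna_noise_sd = 0.02,
                              markers_per_segment_range = c(10L, 50L),
                              target_vote_signal = 7L,
                              target_vote_noise = 2L,
                              n_up_mirnas = 12L, n_down_mirnas = 12L,
                              master_mirna_n_targets = 4L,
                              n_network_genes = 19L,
                              n_overlap_genes = 4L,
                              lib_size_factors = NULL,
                              rng_seed = 1L) {
  d <- as.list(environment())
  stopifnot(
    d$n_tumor >= 2, d$n_normal >= 2,
    d$nb_dispersion >= 0, d$lfc_effect >= 0,
    d$cna_amplitude >= 0,
    d$cna_sample_fraction > 0, d$cna_sample_fraction <= 1,
    d$target_vote_signal >= 0, d$target_vote_signal <= 10,
    d$target_vote_noise >= 0, d$target_vote_noise <= 10,
    d$master_mirna_n_targets <= d$n_network_genes,
    d$n_overlap_genes <= d$n_core_up + d$n_core_down
  )
  n_planted <- d$n_core_up + d$n_core_down + 10L * d$n_decoys_per_layer
  if (n_planted > d$n_genes) stop("more planted genes than n_genes")
  if (d$n_up_mirnas + d$n_down_mirnas > d$n_mirnas) {
    stop("more deregulated miRNAs than n_mirnas")
  }
  class(d) <- "simulation_design"
  d
}

#' Ground truth of a synthetic cohort
#'
#' Deterministically derives, from a design and its seed, which features
#' play which role: core genes per direction, single- and double-layer
#' decoys, planted amplified/deleted genes, deregulated miRNAs with
#' directions, the master miRNA, the network genes, the published-signature
#' overlap genes, and the true miRNA-gene regulatory pairs.
#'
#' @param design A `simulation_design`.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(design) {
  d <- design
  genes <- sprintf("G%04d", seq_len(d$n_genes))
  mirnas <- sprintf("miR.s%03d", seq_len(d$n_mirnas))
  # dedicated stream offset: role assignment must not replay the RNG state
  # an analysis step seeded with the same base seed would see
  set.seed(d$rng_seed + 909L)
  shuffled <- sample(genes)
  take <- local({
    pos <- 0L
    function(n) {
      out <- shuffled[(pos + 1L):(pos + n)]
      pos <<- pos + n
      out
    }
  })
  k <- d$n_decoys_per_layer
  roles <- list(
    core_up = take(d$n_core_up),
    core_down = take(d$n_core_down),
    de_only_up = take(k), de_only_down = take(k),
    cna_only_amp = take(k), cna_only_del = take(k),
    target_only_up = take(k), target_only_down = take(k),
    de_cna_up = take(k), de_cna_down = take(k),
    de_target_up = take(k), de_target_down = take(k)
  )
  # note: cna+target (no DE) decoys reuse the cna_only slots' mirror: add them
  roles$cna_target_amp <- take(k)
  roles$cna_target_del <- take(k)
  mir_shuffled <- sample(mirnas)
  up_mirnas <- mir_shuffled[seq_len(d$n_up_mirnas)]
  down_mirnas <- mir_shuffled[d$n_up_mirnas + seq_len(d$n_down_mirnas)]
  master <- up_mirnas[1]

  # published-signature overlap genes: 1 up-core + rest down-core (if possible)
  n_ov_up <- min(1L, d$n_overlap_genes, d$n_core_up)
  n_ov_down <- min(d$n_overlap_genes - n_ov_up, d$n_core_down)
  overlap <- c(roles$core_up[seq_len(n_ov_up)],
               roles$core_down[seq_len(n_ov_down)])

  # network genes: overlap genes + background (unplanted) genes
  planted_all <- unlist(roles, use.names = FALSE)
  background <- setdiff(genes, planted_all)
  n_bg <- d$n_network_genes - length(overlap)
  network_genes <- c(overlap, sample(background, n_bg))

  # true regulatory pairs, direction-consistent: up gene <- down miRNA,
  # down gene <- up miRNA
  rr <- function(targets, pool) {
    if (length(targets) == 0) return(NULL)
    data.frame(mirna = rep_len(pool, length(targets)), gene = targets,
               stringsAsFactors = FALSE)
  }
  # the master regulates a block of network genes; keep other up-miRNAs off it
  master_targets <- c(overlap[overlap %in% roles$core_down],
                      setdiff(network_genes, planted_all))
  master_targets <- master_targets[seq_len(min(d$master_mirna_n_targets,
                                               length(master_targets)))]
  other_up <- setdiff(up_mirnas, master)
  down_core_rest <- setdiff(roles$core_down, master_targets)
  pairs <- rbind(
    rr(roles$core_up, down_mirnas),
    rr(down_core_rest, other_up),
    data.frame(mirna = master, gene = master_targets,
               stringsAsFactors = FALSE),
    rr(roles$de_target_up, down_mirnas),
    rr(roles$de_target_down, other_up),
    rr(roles$cna_target_amp, down_mirnas),
    rr(roles$cna_target_del, other_up),
    rr(roles$target_only_up, down_mirnas),
    rr(roles$target_only_down, other_up)
  )
  pairs <- unique(pairs)
  truth <- list(
    genes = genes, mirnas = mirnas, roles = roles,
    core_up = roles$core_up, core_down = roles$core_down,
    de_up = c(roles$core_up, roles$de_only_up, roles$de_cna_up,
              roles$de_target_up),
    de_down = c(roles$core_down, roles$de_only_down, roles$de_cna_down,
                roles$de_target_down),
    planted_amplified = c(roles$core_up, roles$cna_only_amp, roles$de_cna_up,
                          roles$cna_target_amp),
    planted_deleted = c(roles$core_down, roles$cna_only_del,
                        roles$de_cna_down, roles$cna_target_del),
    deregulated_mirnas = c(stats::setNames(rep("up", length(up_mirnas)),
                                           up_mirnas),
                           stats::setNames(rep("down", length(down_mirnas)),
                                           down_mirnas)),
    master_mirna = master,
    master_targets = master_targets,
    network_genes = network_genes,
    overlap_genes = overlap,
    true_pairs = pairs
  )
  class(truth) <- "ground_truth"
  truth
}

#' Synthetic genome annotation
#'
#' Lays the design's genes along four synthetic chromosomes (10 kb genes
#' every 20 kb) and places each deregulated miRNA's locus: miRNAs regulating
#' planted core genes sit in neutral territory, except one down-miRNA placed
#' inside a planted deleted gene span and one non-master up-miRNA inside a
#' planted amplified span, so locus-level miRNA copy-number concordance is
#' exercisable.
#'
#' @param design A `simulation_design`.
#' @param truth Matching `ground_truth`.
#' @return A `genome_annotation` with gene and mirna records.
#' @export
generate_annotation <- function(design, truth) {
  n <- design$n_genes
  chrom_of <- paste0("chr", ((seq_len(n) - 1L) %% 4L) + 1L)
  local_idx <- ave(seq_len(n), chrom_of, FUN = seq_along)
  start <- (local_idx - 1L) * 20000L
  genes <- data.frame(feature_id = truth$genes, chrom = chrom_of,
                      start = start, end = start + 10000L,
                      feature_kind = "gene", stringsAsFactors = FALSE)
  dereg <- names(truth$deregulated_mirnas)
  span_of <- function(g) genes[genes$feature_id == g, c("chrom", "start", "end")]
  mir_rows <- lapply(seq_along(dereg), function(i) {
    m <- dereg[i]
    dirn <- truth$deregulated_mirnas[[m]]
    host <- NULL
    if (dirn == "down" && i == which(truth$deregulated_mirnas == "down")[1]) {
      host <- truth$planted_deleted[1]
    }
    up_idx <- which(truth$deregulated_mirnas == "up" &
                      dereg != truth$master_mirna)
    if (dirn == "up" && length(up_idx) > 0 && i == up_idx[1]) {
      host <- truth$planted_amplified[1]
    }
    if (!is.null(host)) {
      sp <- span_of(host)
      data.frame(feature_id = m, chrom = sp$chrom, start = sp$start + 2000L,
                 end = sp$start + 2200L, feature_kind = "mirna",
                 stringsAsFactors = FALSE)
    } else {
      # neutral intergenic placement, in the gaps between chr1 genes
      pos <- 20000L * (i - 1L) + 14000L
      data.frame(feature_id = m, chrom = "chr1", start = pos,
                 end = pos + 200L, feature_kind = "mirna",
                 stringsAsFactors = FALSE)
    }
  })
  genome_annotation(rbind(genes, do.call(rbind, mir_rows)))
}

nb_draw <- function(n, mu, phi) {
  if (phi > 0) stats::rnbinom(n, size = 1 / phi, mu = mu)
  else stats::rpois(n, mu)
}

#' Generate expression count matrices
#'
#' Draws gene and miRNA counts from NB(mu, phi) with per-feature baseline
#' means (log-uniform); planted features have tumor/normal group means
#' differing by exactly `lfc_effect` log2 units in the planted direction
#' (symmetric half-effect up and down from baseline).
#'
#' @param design A `simulation_design`.
#' @param truth Optional matching `ground_truth` (derived if omitted).
#' @return List with `genes` and `mirnas` (`count_matrix` objects).
#' @export
generate_expression <- function(design, truth = ground_truth(design)) {
  d <- design
  n_s <- d$n_tumor + d$n_normal
  samples <- c(sprintf("T%03d", seq_len(d$n_tumor)),
               sprintf("N%03d", seq_len(d$n_normal)))
  cls <- stats::setNames(rep(c("tumor", "normal"), c(d$n_tumor, d$n_normal)),
                         samples)
  lib <- if (is.null(d$lib_size_factors)) rep(1, n_s) else d$lib_size_factors
  stopifnot(length(lib) == n_s)

  draw_matrix <- function(ids, up_ids, down_ids, planted_ids, seed_off) {
    set.seed(d$rng_seed + seed_off)
    n_f <- length(ids)
    lo <- log(d$baseline_mean_range[1]); hi <- log(d$baseline_mean_range[2])
    base <- exp(stats::runif(n_f, lo, hi))
    plo <- log(d$planted_mean_range[1]); phi_ <- log(d$planted_mean_range[2])
    planted <- ids %in% planted_ids
    base[planted] <- exp(stats::runif(sum(planted), plo, phi_))
    lfc <- numeric(n_f)
    lfc[ids %in% up_ids] <- d$lfc_effect
    lfc[ids %in% down_ids] <- -d$lfc_effect
    mu_t <- base * 2^(lfc / 2)
    mu_n <- base * 2^(-lfc / 2)
    counts <- matrix(0L, n_f, n_s, dimnames = list(ids, samples))
    for (j in seq_len(n_s)) {
      mu <- if (cls[j] == "tumor") mu_t else mu_n
      counts[, j] <- nb_draw(n_f, mu * lib[j], d$nb_dispersion)
    }
    count_matrix(counts, cls)
  }
  gene_planted <- c(truth$de_up, truth$de_down)
  mir_dirs <- truth$deregulated_mirnas
  list(
    genes = draw_matrix(truth$genes, truth$de_up, truth$de_down,
                        gene_planted, 101L),
    mirnas = draw_matrix(truth$mirnas,
                         names(mir_dirs)[mir_dirs == "up"],
                         names(mir_dirs)[mir_dirs == "down"],
                         names(mir_dirs), 202L)
  )
}

#' Generate tumor segment profiles
#'
#' For each tumor sample and chromosome, planted amplified (deleted) genes
#' carry a dedicated segment at +`cna_amplitude` (-`cna_amplitude`) in a
#' `cna_sample_fraction` share of samples; the remaining territory is tiled
#' by background segments with mean ~ N(0, `cna_noise_sd`).  Every segment
#' records a marker count drawn from `markers_per_segment_range`.
#'
#' @param design A `simulation_design`.
#' @param truth Matching `ground_truth`.
#' @param annotation Matching `genome_annotation`.
#' @return A `seg_profiles` data.frame covering all tumor samples.
#' @export
generate_segments <- function(design, truth,
                              annotation = generate_annotation(design, truth)) {
  d <- design
  set.seed(d$rng_seed + 303L)
  genes <- annotation[annotation$feature_kind == "gene", , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  mk <- function(n) {
    sample(seq(d$markers_per_segment_range[1], d$markers_per_segment_range[2]),
           n, replace = TRUE)
  }
  rows <- vector("list", d$n_tumor * 8L)
  ri <- 0L
  for (s in sprintf("T%03d", seq_len(d$n_tumor))) {
    for (ch in unique(genes$chrom)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      amp <- g$feature_id %in% truth$planted_amplified &
        stats::runif(nrow(g)) < d$cna_sample_fraction
      del <- g$feature_id %in% truth$planted_deleted &
        stats::runif(nrow(g)) < d$cna_sample_fraction
      ev <- which(amp | del)
      chrom_end <- max(g$end) + 10000L
      bounds_start <- integer(0); bounds_end <- integer(0); means <- numeric(0)
      cur <- 0L
      for (i in ev) {
        seg_s <- g$start[i] - 2000L
        seg_e <- g$end[i] + 2000L
        if (seg_s > cur) {
          bounds_start <- c(bounds_start, cur)
          bounds_end <- c(bounds_end, seg_s)
          means <- c(means, stats::rnorm(1, 0, d$cna_noise_sd))
        }
        bounds_start <- c(bounds_start, seg_s)
        bounds_end <- c(bounds_end, seg_e)
        means <- c(means, if (amp[i]) d$cna_amplitude else -d$cna_amplitude)
        cur <- seg_e
      }
      if (cur < chrom_end) {
        bounds_start <- c(bounds_start, cur)
        bounds_end <- c(bounds_end, chrom_end)
        means <- c(means, stats::rnorm(1, 0, d$cna_noise_sd))
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(sample = s, chrom = ch, start = bounds_start,
                               end = bounds_end, n_markers = mk(length(means)),
                               seg_mean = means, stringsAsFactors = FALSE)
    }
  }
  seg_profiles(do.call(rbind, rows[seq_len(ri)]))
}

#' Generate the multi-database target table
#'
#' Every true regulatory pair of the ground truth receives
#' `target_vote_signal` votes from distinct databases; spurious
#' (noise) pairs receive `target_vote_noise` votes.  Database names come
#' from the 10-database consensus universe.
#'
#' @param design A `simulation_design`.
#' @param truth Matching `ground_truth`.
#' @param n_noise_pairs Number of spurious pairs (default: twice the number
#'   of true pairs).
#' @return data.frame of (mirna, gene, database) triples.
#' @export
generate_target_db <- function(design, truth,
                               n_noise_pairs = 2L * nrow(truth$true_pairs)) {
  d <- design
  set.seed(d$rng_seed + 404L)
  vote_rows <- function(pairs, votes) {
    if (votes == 0 || nrow(pairs) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      data.frame(mirna = pairs$mirna[i], gene = pairs$gene[i],
                 database = sample(TARGET_DATABASES, votes),
                 stringsAsFactors = FALSE)
    }))
  }
  true_key <- paste(truth$true_pairs$mirna, truth$true_pairs$gene)
  noise <- data.frame(
    mirna = sample(truth$mirnas, n_noise_pairs, replace = TRUE),
    gene = sample(truth$genes, n_noise_pairs, replace = TRUE),
    stringsAsFactors = FALSE)
  noise <- unique(noise[!(paste(noise$mirna, noise$gene) %in% true_key), ,
                        drop = FALSE])
  out <- rbind(vote_rows(truth$true_pairs, d$target_vote_signal),
               vote_rows(noise, d$target_vote_noise))
  if (is.null(out)) {
    out <- data.frame(mirna = character(), gene = character(),
                      database = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Generate the synthetic co-expression network
#'
#' A connected edge list over the truth's network genes: a spanning path
#' through a seeded shuffle of the genes plus random chords.
#'
#' @param design A `simulation_design`.
#' @param truth Matching `ground_truth`.
#' @return Edge data.frame (entity1, entity2, provenance).
#' @export
generate_network <- function(design, truth) {
  set.seed(design$rng_seed + 505L)
  g <- sample(truth$network_genes)
  edges <- data.frame(entity1 = g[-length(g)], entity2 = g[-1],
                      stringsAsFactors = FALSE)
  n_extra <- max(2L, length(g) %/% 2L)
  for (i in seq_len(n_extra)) {
    pair <- sample(g, 2)
    edges <- rbind(edges, data.frame(entity1 = pair[1], entity2 = pair[2]))
  }
  lo <- pmin(edges$entity1, edges$entity2)
  hi <- pmax(edges$entity1, edges$entity2)
  keep <- !duplicated(paste(lo, hi))
  data.frame(entity1 = lo[keep], entity2 = hi[keep],
             provenance = "synthetic-coexpression", stringsAsFactors = FALSE)
}

#' Generate a complete cohort in memory
#'
#' @param design A `simulation_design`.
#' @return List: design, truth, annotation, expression (genes, mirnas),
#'   segments, targets, network, signatures (named list of gene vectors).
#' @export
generate_cohort <- function(design) {
  truth <- ground_truth(design)
  annotation <- generate_annotation(design, truth)
  expr <- generate_expression(design, truth)
  segments <- generate_segments(design, truth, annotation)
  targets <- generate_target_db(design, truth)
  network <- generate_network(design, truth)
  set.seed(design$rng_seed + 606L)
  planted_all <- unlist(truth$roles, use.names = FALSE)
  filler_pool <- setdiff(truth$genes, planted_all)
  signatures <- lapply(seq_along(truth$overlap_genes), function(i) {
    c(truth$overlap_genes[i], sample(filler_pool, 5))
  })
  names(signatures) <- paste0("signature_", seq_along(signatures))
  list(design = design, truth = truth, annotation = annotation,
       expression = expr, segments = segments, targets = targets,
       network = network, signatures = signatures)
}

#' Write a cohort directory
#'
#' Emits every file the pipeline readers consume: gene and miRNA count
#' matrices with labels, tumor SEG profiles, a BED annotation, the target
#' table, the network edge list, one published-signature file per overlap
#' gene, and the ground truth as JSON.
#'
#' @param design A `simulation_design` (or a ready `generate_cohort()` list).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` and the in-memory `cohort`.
#' @export
write_cohort <- function(design, dir) {
  cohort <- if (inherits(design, "simulation_design")) {
    generate_cohort(design)
  } else design
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "signatures"), showWarnings = FALSE)
  p <- list(
    counts = file.path(dir, "gene_counts.tsv"),
    labels = file.path(dir, "labels.tsv"),
    mirna_counts = file.path(dir, "mirna_counts.tsv"),
    mirna_labels = file.path(dir, "mirna_labels.tsv"),
    seg = file.path(dir, "segments.seg"),
    bed = file.path(dir, "annotation.bed"),
    targets = file.path(dir, "targets.tsv"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_count_matrix(cohort$expression$genes, p$counts, p$labels)
  write_count_matrix(cohort$expression$mirnas, p$mirna_counts, p$mirna_labels)
  write_seg(cohort$segments, p$seg)
  write_bed(cohort$annotation, p$bed)
  write_target_db(cohort$targets, p$targets)
  write_network_edges(cohort$network, p$network)
  p$signatures <- vapply(names(cohort$signatures), function(nm) {
    f <- file.path(dir, "signatures", paste0(nm, ".txt"))
    writeLines(cohort$signatures[[nm]], f)
    f
  }, "")
  truth_json <- unclass(cohort$truth)
  truth_json$roles <- NULL
  jsonlite::write_json(truth_json, p$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = p, cohort = cohort))
}

#' Read a ground-truth JSON back
#' @param path Path to truth.json.
#' @return List of class `ground_truth` (without the role breakdown).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$deregulated_mirnas <- unlist(tr$deregulated_mirnas)
  class(tr) <- "ground_truth"
  tr
}
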