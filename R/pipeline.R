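#' Run the full integrative workflow
#'
#' Executes every stage in order on a cohort: quantile filtering and
#' exact-NB differential expression for genes and miRNAs, segment hygiene
#' and gene-level copy-number calling with permutation q-values,
#' multi-database target consensus, the direction-consistent layer
#' intersections down to core genes, published-signature overlap, network
#' enrichment with master-miRNA ranking, and (optionally) cross-validated
#' AUC evaluation of the candidate feature sets.  When the cohort carries a
#' ground truth, planted-signal precision/recall are scored into the report.
#'
#' @param cohort A `generate_cohort()` list, a `simulation_design`, or a
#'   cohort directory written by [write_cohort()].
#' @param config An `analysis_config`.
#' @param classify Run the classification stage (approaches I-VI).
#' @param out_dir Optional directory for stage artifacts (TSV tables and the
#'   JSON report); NULL writes nothing.
#' @return A `run_report` list; see the fields written by the function.
#' @export
run_all <- function(cohort, config = analysis_config(), classify = TRUE,
                    out_dir = NULL) {
  if (inherits(cohort, "simulation_design")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  truth <- cohort$truth

  # 1. filter + differential expression, genes and miRNAs
  genes_f <- quantile_filter(cohort$expression$genes, config$quantile_cut)
  mirnas_f <- quantile_filter(cohort$expression$mirnas, config$quantile_cut)
  de_genes <- call_degs(genes_f, config)
  de_mirnas <- call_degs(mirnas_f, config)

  # 2. copy number
  seg <- merge_small_segments(cohort$segments, config$min_markers)
  scores <- gene_level_scores(seg, cohort$annotation,
                              config$cna_gain_threshold,
                              config$cna_loss_threshold)
  qv <- permutation_q(scores, cohort$annotation, config$n_perm,
                      config$rng_seed, config$cna_gain_threshold,
                      config$cna_loss_threshold)
  cna <- call_cna_genes(scores, qv, config)
  mirna_dirs <- c(stats::setNames(rep("up", length(de_mirnas$up)),
                                  de_mirnas$up),
                  stats::setNames(rep("down", length(de_mirnas$down)),
                                  de_mirnas$down))
  mirna_cna <- mirna_cna_overlap(mirna_dirs, cna, cohort$annotation)

  # 3. consensus targets
  cons <- consensus(cohort$targets, config$consensus_min_votes)

  # 4. integration
  ec <- intersect_expression_cna(de_genes$up, de_genes$down,
                                 cna$amplified, cna$deleted)
  ct <- intersect_cna_targets(cna$amplified, cna$deleted, cons,
                              de_mirnas$up, de_mirnas$down)
  et <- intersect_expression_targets(de_genes$up, de_genes$down, cons,
                                     de_mirnas$up, de_mirnas$down)
  core <- core_genes(ec$up_amplified, ec$down_deleted, cons,
                     de_mirnas$up, de_mirnas$down)
  venn <- list(
    up = venn_summary(de_genes$up, cna$amplified,
                      targets_of(cons, de_mirnas$down)),
    down = venn_summary(de_genes$down, cna$deleted,
                        targets_of(cons, de_mirnas$up))
  )

  # 5. published-signature overlap
  overlap <- if (length(cohort$signatures) > 0) {
    sig_files <- vapply(names(cohort$signatures), function(nm) {
      f <- file.path(tempdir(), paste0("coremir_", nm, ".txt"))
      writeLines(cohort$signatures[[nm]], f)
      f
    }, "")
    signature_overlap(core$gene_id, sig_files)
  } else {
    data.frame(gene_id = character(), signatures = character())
  }

  # 6. network enrichment; the background is every gene with at least one
  # consensus annotation plus the network genes themselves
  net_genes <- network_gene_set(cohort$network)
  universe <- union(names(cons$reverse), net_genes)
  cons_dereg <- cons
  keep_m <- intersect(names(cons$forward), c(de_mirnas$up, de_mirnas$down))
  cons_dereg$forward <- cons$forward[keep_m]
  enrich <- fisher_enrichment(cons_dereg, net_genes, universe,
                              config$fisher_alpha)
  masters <- rank_master_mirnas(enrich)
  top_mirna <- if (nrow(masters) > 0) masters$mirna_id[1] else NA_character_

  report <- list(
    config = unclass(config),
    counts = list(
      genes_total = nrow(cohort$expression$genes$counts),
      genes_filtered = nrow(genes_f$counts),
      mirnas_filtered = nrow(mirnas_f$counts),
      de_up = length(de_genes$up), de_down = length(de_genes$down),
      mirna_up = length(de_mirnas$up), mirna_down = length(de_mirnas$down),
      amplified = length(cna$amplified), deleted = length(cna$deleted),
      up_amplified = length(ec$up_amplified),
      down_deleted = length(ec$down_deleted),
      amplified_target_of_down = length(ct$amplified_target_of_down),
      deleted_target_of_up = length(ct$deleted_target_of_up),
      up_target_of_down = length(et$up_target_of_down),
      down_target_of_up = length(et$down_target_of_up),
      core_genes = nrow(core),
      overlap_genes = nrow(overlap),
      network_genes = length(net_genes),
      enriched_mirnas = sum(enrich$enriched),
      mirna_cna_concordant = nrow(mirna_cna)
    ),
    top_mirna = top_mirna,
    venn = venn,
    de = de_genes, de_mirnas = de_mirnas, cna = cna,
    consensus = cons, core = core, overlap = overlap,
    enrichment = enrich, masters = masters, mirna_cna = mirna_cna
  )

  # invariant guard: the containment chain must hold on every run
  stopifnot(
    all(ec$up_amplified %in% de_genes$up),
    all(ec$down_deleted %in% de_genes$down),
    all(core$gene_id[core$direction == "up"] %in% ec$up_amplified),
    all(core$gene_id[core$direction == "down"] %in% ec$down_deleted),
    length(intersect(de_genes$up, de_genes$down)) == 0,
    length(intersect(cna$amplified, cna$deleted)) == 0
  )

  # 7. classification of the candidate feature sets
  if (classify) {
    labels <- cohort$expression$genes$sample_class
    fs <- list(
      I = union(de_genes$up, de_genes$down),
      II = union(ec$up_amplified, ec$down_deleted),
      III = core$gene_id,
      IV = overlap$gene_id,
      V = intersect(net_genes, rownames(cohort$expression$genes$counts))
    )
    report$classification <- lapply(names(fs), function(a) {
      if (length(fs[[a]]) == 0) return(NULL)
      cv_auc(build_feature_matrix(fs[[a]], cohort$expression$genes),
             labels, config, approach_id = a)
    })
    names(report$classification) <- names(fs)
    if (!is.na(top_mirna) &&
        top_mirna %in% rownames(cohort$expression$mirnas$counts)) {
      report$classification$VI <-
        cv_auc(build_feature_matrix(top_mirna, cohort$expression$mirnas),
               cohort$expression$mirnas$sample_class, config,
               approach_id = "VI")
    }
  }

  # 8. planted-truth scoring
  if (!is.null(truth)) {
    pr <- function(called, planted) {
      tp <- length(intersect(called, planted))
      list(precision = if (length(called) > 0) tp / length(called) else NA,
           recall = if (length(planted) > 0) tp / length(planted) else NA)
    }
    truth_core <- c(truth$core_up, truth$core_down)
    master_rank <- if (nrow(masters) > 0) {
      pos <- match(truth$master_mirna, masters$mirna_id)
      if (is.na(pos)) NA_integer_ else pos
    } else NA_integer_
    report$truth_scores <- list(
      core = pr(core$gene_id, truth_core),
      de_up = pr(de_genes$up, truth$de_up),
      de_down = pr(de_genes$down, truth$de_down),
      amplified = pr(cna$amplified, truth$planted_amplified),
      deleted = pr(cna$deleted, truth$planted_deleted),
      master_mirna_rank = master_rank
    )
  }
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(de_genes$table, file.path(out_dir, "de_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de_mirnas$table, file.path(out_dir, "de_mirnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cna$table, file.path(out_dir, "cna_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(core, file.path(out_dir, "core_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' Summarize a run report as plain lists (JSON-ready)
#' @param report A `run_report`.
#' @return Nested list of counts, top miRNA, truth scores and mean AUCs.
#' @export
report_summary <- function(report) {
  out <- list(config = report$config, counts = report$counts,
              top_mirna = report$top_mirna,
              venn = lapply(report$venn, as.list))
  if (!is.null(report$classification)) {
    out$auc_mean <- lapply(
      Filter(Negate(is.null), report$classification),
      function(r) r$auc_mean)
  }
  if (!is.null(report$truth_scores)) out$truth_scores <- report$truth_scores
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("Integrative run report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-26s %d\n", nm, x$counts[[nm]]))
  }
  cat("  top miRNA:", x$top_mirna, "\n")
  if (!is.null(x$truth_scores)) {
    cat(sprintf("  core precision %.3f recall %.3f; master rank %s\n",
                x$truth_scores$core$precision, x$truth_scores$core$recall,
                format(x$truth_scores$master_mirna_rank)))
  }
  invisible(x)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A cohort list (same shape as [generate_cohort()]).
#' @export
read_cohort <- function(dir) {
  sig_files <- list.files(file.path(dir, "signatures"), full.names = TRUE)
  signatures <- lapply(sig_files, read_signature)
  names(signatures) <- sub("\\.txt$", "", basename(sig_files))
  truth_path <- file.path(dir, "truth.json")
  list(
    expression = list(
      genes = read_count_matrix(file.path(dir, "gene_counts.tsv"),
                                file.path(dir, "labels.tsv")),
      mirnas = read_count_matrix(file.path(dir, "mirna_counts.tsv"),
                                 file.path(dir, "mirna_labels.tsv"))
    ),
    segments = read_seg(file.path(dir, "segments.seg")),
    annotation = read_bed(file.path(dir, "annotation.bed")),
    targets = read_target_db(file.path(dir, "targets.tsv")),
    network = read_network_edges(file.path(dir, "network.tsv")),
    signatures = signatures,
    truth = if (file.exists(truth_path)) read_truth(truth_path) else NULL
  )
}

#' Re-derive the published worked example from the packaged table fixtures
#'
#' The package ships machine-readable transcriptions of the printed result
#' tables of the source study (expression-CNA gene list, core-gene list with
#' regulating miRNAs, published signatures, co-expression edge list, cohort
#' characteristics).  This function re-runs the integration operations on
#' those fixtures and returns every aggregate: the expression-CNA
#' intersection sizes, the core-gene accounting, the four-gene signature
#' overlap, the network gene count, and the cohort size by both
#' stratifications.
#'
#' @param fixtures_dir Directory with the fixtures (defaults to the
#'   installed package's `extdata`).
#' @return Nested list of recomputed aggregates.
#' @export
validate_tables <- function(fixtures_dir = system.file("extdata",
                                                       package = "coremir")) {
  t1 <- utils::read.delim(file.path(fixtures_dir, "table1_expression_cna.tsv"),
                          stringsAsFactors = FALSE)
  t2 <- utils::read.delim(file.path(fixtures_dir, "table2_core_genes.tsv"),
                          stringsAsFactors = FALSE)
  t5 <- utils::read.delim(file.path(fixtures_dir, "table5_cohort.tsv"),
                          stringsAsFactors = FALSE)
  edges <- read_network_edges(file.path(fixtures_dir,
                                        "table4_coexpression_edges.tsv"))

  up_genes <- t1$gene[t1$alteration == "up_amplified"]
  down_genes <- t1$gene[t1$alteration == "down_deleted"]
  # expression/CNA layers coincide in the printed list; the intersection
  # operation still runs for the accounting
  ec <- intersect_expression_cna(up_genes, down_genes, up_genes, down_genes)

  # rebuild a consensus object from the printed core-gene regulator table:
  # each printed pair is voted by the minimum consensus number of databases
  pair_list <- lapply(seq_len(nrow(t2)), function(i) {
    mirs <- trimws(strsplit(t2$mirnas[i], ",")[[1]])
    data.frame(mirna = mirs, gene = t2$gene[i], stringsAsFactors = FALSE)
  })
  pairs <- unique(do.call(rbind, pair_list))
  triples <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(mirna = pairs$mirna[i], gene = pairs$gene[i],
               database = TARGET_DATABASES[1:5], stringsAsFactors = FALSE)
  }))
  cons <- consensus(triples, min_votes = 5L)
  # direction logic: an up/amplified gene is regulated by down-miRNAs and a
  # down/deleted gene by up-miRNAs
  down_mirnas <- unique(pairs$mirna[pairs$gene %in% up_genes])
  up_mirnas <- unique(pairs$mirna[pairs$gene %in% down_genes])
  core <- core_genes(ec$up_amplified, ec$down_deleted, cons,
                     up_mirnas, down_mirnas)

  sig_files <- list.files(fixtures_dir, pattern = "^table3_signature_",
                          full.names = TRUE)
  overlap <- signature_overlap(core$gene_id, sig_files)

  mir_targets <- utils::read.delim(
    file.path(fixtures_dir, "network_mirna_targets.tsv"),
    stringsAsFactors = FALSE)
  net_genes <- network_gene_set(edges)
  top_mir <- unique(mir_targets$mirna)[1]
  top_mir_in_net <- intersect(mir_targets$gene[mir_targets$mirna == top_mir],
                              net_genes)

  list(
    table1 = list(n_genes = length(unique(t1$gene)),
                  up_amplified = length(ec$up_amplified),
                  down_deleted = length(ec$down_deleted)),
    table2 = list(n_core = nrow(core),
                  up_amplified = sum(core$direction == "up"),
                  down_deleted = sum(core$direction == "down")),
    signature_overlap = list(n = nrow(overlap), genes = overlap$gene_id),
    table4 = list(n_edges = nrow(edges), n_genes = length(net_genes)),
    network_mirna = list(id = top_mir,
                         n_network_targets = length(top_mir_in_net)),
    table5 = list(
      pc_by_age = sum(t5$pc[t5$stratification == "age"]),
      controls_by_age = sum(t5$controls[t5$stratification == "age"]),
      pc_by_gleason = sum(t5$pc[t5$stratification == "gleason"]),
      controls = sum(t5$controls[t5$stratification == "age"])
    )
  )
}
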