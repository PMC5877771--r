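#' Join under-supported segments to their nearest neighbor in copy number
#'
#' Iteratively absorbs the segment with the fewest markers (below
#' `min_markers`) into the adjacent same-chromosome neighbor whose segment
#' mean is closest; the absorbed span and marker count are added to the
#' neighbor and the neighbor's mean becomes the marker-weighted mean.  Ties
#' in closeness go to the left (earlier-coordinate) neighbor.  Total marker
#' count per chromosome is conserved.
#'
#' @param seg A `seg_profiles` data.frame.
#' @param min_markers Segments with fewer markers than this are absorbed.
#' @return A `seg_profiles` data.frame with no segment below `min_markers`
#'   (unless a chromosome has a single segment left).
#' @export
merge_small_segments <- function(seg, min_markers = 4L) {
  stopifnot(inherits(seg, "seg_profiles") || is.data.frame(seg))
  merge_block <- function(blk) {
    blk <- blk[order(blk$start), , drop = FALSE]
    repeat {
      small <- which(blk$n_markers < min_markers)
      if (length(small) == 0 || nrow(blk) == 1) break
      i <- small[which.min(blk$n_markers[small])]
      left_d <- if (i > 1) abs(blk$seg_mean[i - 1] - blk$seg_mean[i]) else Inf
      right_d <- if (i < nrow(blk)) abs(blk$seg_mean[i + 1] - blk$seg_mean[i]) else Inf
      j <- if (left_d <= right_d) i - 1L else i + 1L
      w <- blk$n_markers[c(i, j)]
      blk$seg_mean[j] <- sum(blk$seg_mean[c(i, j)] * w) / sum(w)
      blk$n_markers[j] <- sum(w)
      blk$start[j] <- min(blk$start[c(i, j)])
      blk$end[j] <- max(blk$end[c(i, j)])
      blk <- blk[-i, , drop = FALSE]
    }
    if (any(blk$n_markers < min_markers)) {
      warning("chromosome ", blk$chrom[1], " of sample ", blk$sample[1],
              " has fewer than ", min_markers, " markers in total")
    }
    blk
  }
  parts <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  out <- do.call(rbind, lapply(parts, merge_block))
  seg_profiles(out)
}

# per-gene, per-sample marker-weighted mean segment log2 ratio
# returns genes x samples matrix; genes without overlap get 0
gene_amplitude_matrix <- function(seg, annotation) {
  genes <- annotation[annotation$feature_kind == "gene", , drop = FALSE]
  samples <- unique(seg$sample)
  amp <- matrix(0, nrow(genes), length(samples),
                dimnames = list(genes$feature_id, samples))
  if (nrow(seg) == 0 || nrow(genes) == 0) return(amp)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  for (s in samples) {
    blk <- seg[seg$sample == s, , drop = FALSE]
    gr_seg <- GenomicRanges::GRanges(
      blk$chrom, IRanges::IRanges(blk$start + 1L, blk$end))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- blk$n_markers[si]
    num <- tapply(w * blk$seg_mean[si], qi, sum)
    den <- tapply(w, qi, sum)
    amp[as.integer(names(num)), s] <- num / den
  }
  amp
}

#' Gene-level amplification and deletion scores
#'
#' For every annotated gene and sample, the amplitude is the marker-weighted
#' mean segment log2 ratio over the gene span.  The amplification score
#' g_amp is the across-sample mean of the positive amplitudes restricted to
#' samples whose amplitude exceeds `gain_threshold` (frequency x amplitude,
#' the G-score construction); g_del mirrors it below `loss_threshold`.
#' Genes with no overlapping segment score 0.
#'
#' @param seg Merged `seg_profiles`.
#' @param annotation A `genome_annotation` (gene records are used).
#' @param gain_threshold,loss_threshold Log2-ratio thresholds (+/-0.1).
#' @return data.frame with gene_id, g_amp, g_del plus the amplitude matrix
#'   as attribute "amplitude".
#' @export
gene_level_scores <- function(seg, annotation,
                              gain_threshold = 0.1, loss_threshold = -0.1) {
  amp <- gene_amplitude_matrix(seg, annotation)
  n <- ncol(amp)
  g_amp <- if (n > 0) rowSums(amp * (amp > gain_threshold)) / n else rep(0, nrow(amp))
  g_del <- if (n > 0) rowSums(-amp * (amp < loss_threshold)) / n else rep(0, nrow(amp))
  out <- data.frame(gene_id = rownames(amp), g_amp = unname(pmax(g_amp, 0)),
                    g_del = unname(pmax(g_del, 0)), stringsAsFactors = FALSE)
  attr(out, "amplitude") <- amp
  out
}

#' Permutation q-values for gene-level copy-number scores
#'
#' Null scores are generated by independently circularly shifting each
#' sample's gene-level amplitude vector (genes in genomic order) by a
#' uniform random offset, preserving each sample's amplitude distribution
#' and local autocorrelation.  Per-gene p-values compare the observed score
#' with the null scores pooled over all genes and permutations,
#' p = (1 + #{null >= observed}) / (1 + n_null); q-values are BH over genes.
#'
#' @param scores Output of [gene_level_scores()] (with amplitude attribute).
#' @param annotation Genome annotation supplying genomic gene order.
#' @param n_perm Number of permutations (>= 20).
#' @param seed Integer seed.
#' @param gain_threshold,loss_threshold As in [gene_level_scores()].
#' @return data.frame gene_id, q_amp, q_del (plus p_amp, p_del).
#' @export
permutation_q <- function(scores, annotation, n_perm = 200L, seed = 1L,
                          gain_threshold = 0.1, loss_threshold = -0.1) {
  if (n_perm < 20L) stop("n_perm must be >= 20 (unstable null below that)")
  amp <- attr(scores, "amplitude")
  stopifnot(!is.null(amp))
  genes <- annotation[annotation$feature_kind == "gene", , drop = FALSE]
  ord <- order(genes$chrom, genes$start)
  amp <- amp[genes$feature_id[ord], , drop = FALSE]
  n_genes <- nrow(amp); n_samp <- ncol(amp)
  set.seed(seed)
  null_amp <- numeric(n_perm * n_genes)
  null_del <- numeric(n_perm * n_genes)
  for (b in seq_len(n_perm)) {
    shifted <- amp
    offs <- sample.int(n_genes, n_samp, replace = TRUE) - 1L
    for (j in seq_len(n_samp)) {
      if (offs[j] > 0) {
        shifted[, j] <- amp[c((offs[j] + 1L):n_genes, 1L:offs[j]), j]
      }
    }
    idx <- ((b - 1L) * n_genes + 1L):(b * n_genes)
    null_amp[idx] <- rowSums(shifted * (shifted > gain_threshold)) / n_samp
    null_del[idx] <- rowSums(-shifted * (shifted < loss_threshold)) / n_samp
  }
  obs <- scores[match(rownames(amp), scores$gene_id), , drop = FALSE]
  p_amp <- (1 + vapply(obs$g_amp, function(g) sum(null_amp >= g), numeric(1))) /
    (1 + length(null_amp))
  p_del <- (1 + vapply(obs$g_del, function(g) sum(null_del >= g), numeric(1))) /
    (1 + length(null_del))
  out <- data.frame(gene_id = rownames(amp),
                    p_amp = p_amp, p_del = p_del,
                    q_amp = bh_adjust(p_amp), q_del = bh_adjust(p_del),
                    stringsAsFactors = FALSE)
  out[match(scores$gene_id, out$gene_id), , drop = FALSE]
}

#' Call amplified and deleted genes
#'
#' A gene is amplified when q_amp < `q_threshold` and its amplification
#' score is positive; deleted mirrored.  A gene significant in both
#' directions is set to neutral with a warning.
#'
#' @param scores Output of [gene_level_scores()].
#' @param qvalues Output of [permutation_q()].
#' @param config An `analysis_config`.
#' @return List with `amplified`, `deleted` (character vectors) and `table`
#'   (gene_id, g_amp, g_del, q_amp, q_del, status).
#' @export
call_cna_genes <- function(scores, qvalues, config = analysis_config()) {
  tab <- merge(scores, qvalues[, c("gene_id", "q_amp", "q_del")],
               by = "gene_id", sort = FALSE)
  amp <- tab$q_amp < config$cna_q_threshold & tab$g_amp > 0
  del <- tab$q_del < config$cna_q_threshold & tab$g_del > 0
  both <- amp & del
  if (any(both)) {
    warning(sum(both), " gene(s) significant in both directions; set neutral")
    amp[both] <- FALSE
    del[both] <- FALSE
  }
  tab$status <- ifelse(amp, "amplified", ifelse(del, "deleted", "neutral"))
  list(amplified = tab$gene_id[amp], deleted = tab$gene_id[del], table = tab)
}

#' miRNAs whose own locus carries a direction-concordant CNA
#'
#' Returns downregulated miRNAs whose annotated locus overlaps a deleted
#' gene call and upregulated miRNAs overlapping an amplified call (the
#' pri/pre-miRNA copy-number concordance check).
#'
#' @param mirna_directions Named character vector, miRNA id -> "up"/"down".
#' @param cna_calls Result of [call_cna_genes()].
#' @param annotation `genome_annotation` with `mirna` (loci) and `gene` rows.
#' @return data.frame mirna_id, direction, cna.
#' @export
mirna_cna_overlap <- function(mirna_directions, cna_calls, annotation) {
  mir <- annotation[annotation$feature_kind == "mirna", , drop = FALSE]
  mir <- mir[mir$feature_id %in% names(mirna_directions), , drop = FALSE]
  empty <- data.frame(mirna_id = character(), direction = character(),
                      cna = character(), stringsAsFactors = FALSE)
  if (nrow(mir) == 0) {
    warning("no miRNA loci annotated")
    return(empty)
  }
  genes <- annotation[annotation$feature_kind == "gene", , drop = FALSE]
  genes <- genes[genes$feature_id %in%
                   c(cna_calls$amplified, cna_calls$deleted), , drop = FALSE]
  if (nrow(genes) == 0) return(empty)
  gr_mir <- GenomicRanges::GRanges(mir$chrom,
                                   IRanges::IRanges(mir$start + 1L, mir$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_mir, gr_gene)
  if (length(hits) == 0) return(empty)
  res <- data.frame(
    mirna_id = mir$feature_id[S4Vectors::queryHits(hits)],
    gene_status = ifelse(genes$feature_id[S4Vectors::subjectHits(hits)] %in%
                           cna_calls$amplified, "amplified", "deleted"),
    stringsAsFactors = FALSE)
  res$direction <- unname(mirna_directions[res$mirna_id])
  keep <- (res$direction == "down" & res$gene_status == "deleted") |
    (res$direction == "up" & res$gene_status == "amplified")
  res <- res[keep, , drop = FALSE]
  res <- unique(data.frame(mirna_id = res$mirna_id, direction = res$direction,
                           cna = res$gene_status, stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}
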