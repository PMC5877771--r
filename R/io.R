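#' Construct a labeled count matrix
#'
#' The central expression container: a non-negative integer matrix of
#' features x samples with a tumor/normal class per sample and an optional
#' Gleason stratum tag.
#'
#' @param counts Integer matrix with unique rownames (feature ids) and
#'   colnames (sample ids).
#' @param sample_class Named character vector mapping every sample id to
#'   "tumor" or "normal".
#' @param gleason Optional named integer vector of Gleason scores.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_class, gleason = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  sample_class <- sample_class[colnames(counts)]
  if (anyNA(names(sample_class)) || anyNA(sample_class)) {
    stop("every sample needs a class label")
  }
  if (!all(sample_class %in% c("tumor", "normal"))) {
    stop("sample classes must be 'tumor' or 'normal'")
  }
  obj <- list(counts = counts, sample_class = sample_class, gleason = gleason)
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$sample_class)
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by sample ids
#' @param x A `count_matrix`.
#' @param sample_ids Sample ids to keep, in order.
#' @return A `count_matrix` restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(all(sample_ids %in% colnames(x$counts)))
  count_matrix(x$counts[, sample_ids, drop = FALSE],
               x$sample_class[sample_ids],
               if (!is.null(x$gleason)) x$gleason[sample_ids])
}

#' Read and write labeled count matrices
#'
#' Counts live in a TSV with a header row of sample ids and feature ids in
#' the first column; labels in a two-column TSV (`sample`, `class`) with an
#' optional `gleason` column.  Cells must be non-negative integers.
#'
#' @param path Path to the counts TSV.
#' @param labels_path Path to the labels TSV.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, labels_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicate feature id in ", path)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  if (!is.numeric(counts) || any(counts != round(counts)) || any(counts < 0)) {
    stop("counts file contains non-integer or negative values: ", path)
  }
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "class") %in% names(lab))) {
    stop("labels file needs 'sample' and 'class' columns")
  }
  missing <- setdiff(colnames(counts), lab$sample)
  if (length(missing) > 0) {
    stop("samples missing from labels: ", paste(missing, collapse = ", "))
  }
  cls <- stats::setNames(lab$class, lab$sample)[colnames(counts)]
  gl <- NULL
  if ("gleason" %in% names(lab)) {
    gl <- stats::setNames(suppressWarnings(as.integer(lab$gleason)),
                          lab$sample)[colnames(counts)]
  }
  count_matrix(counts, cls, gl)
}

#' @rdname read_count_matrix
#' @param x A `count_matrix`.
#' @export
write_count_matrix <- function(x, path, labels_path) {
  out <- data.frame(feature = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample = colnames(x$counts),
                    class = unname(x$sample_class),
                    stringsAsFactors = FALSE)
  if (!is.null(x$gleason)) lab$gleason <- unname(x$gleason[lab$sample])
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write segmented copy-number profiles (SEG)
#'
#' SEG files carry columns Sample, Chromosome, Start, End, Num_Probes,
#' Segment_Mean with 1-based inclusive coordinates on disk.  In memory all
#' coordinates are 0-based half-open; per sample and chromosome the segments
#' are sorted and must not overlap.
#'
#' @param path Path to a SEG file.
#' @return A data.frame of class `seg_profiles` with columns `sample`,
#'   `chrom`, `start`, `end` (0-based half-open), `n_markers`, `seg_mean`.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  if (!all(need %in% names(tab))) {
    stop("SEG file must have columns ", paste(need, collapse = ", "))
  }
  seg <- data.frame(sample = as.character(tab$Sample),
                    chrom = as.character(tab$Chromosome),
                    start = as.integer(tab$Start) - 1L,
                    end = as.integer(tab$End),
                    n_markers = as.integer(tab$Num_Probes),
                    seg_mean = as.numeric(tab$Segment_Mean),
                    stringsAsFactors = FALSE)
  seg_profiles(seg)
}

#' @rdname read_seg
#' @param seg A `seg_profiles` data.frame (0-based half-open internal
#'   coordinates); converted back to 1-based inclusive on disk.
#' @export
write_seg <- function(seg, path) {
  out <- data.frame(Sample = seg$sample, Chromosome = seg$chrom,
                    Start = seg$start + 1L, End = seg$end,
                    Num_Probes = seg$n_markers, Segment_Mean = seg$seg_mean)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a segment table as a `seg_profiles` object
#' @param seg data.frame with columns sample, chrom, start, end, n_markers,
#'   seg_mean (0-based half-open).
#' @return The sorted, validated data.frame with class `seg_profiles`.
#' @export
seg_profiles <- function(seg) {
  stopifnot(all(c("sample", "chrom", "start", "end", "n_markers", "seg_mean")
                %in% names(seg)))
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  if (any(seg$n_markers < 1L)) stop("segment with fewer than 1 marker")
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  by_sc <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  for (blk in by_sc) {
    if (nrow(blk) > 1 && any(blk$start[-1] < blk$end[-nrow(blk)])) {
      stop("overlapping segments within sample ", blk$sample[1],
           " chromosome ", blk$chrom[1])
    }
  }
  class(seg) <- c("seg_profiles", "data.frame")
  seg
}

#' Read and write genome annotation (BED6)
#'
#' BED is 0-based half-open on disk, matching the internal convention.  The
#' name column carries the feature id, the score column is unused (0) and the
#' strand is recorded but ignored by all overlap computations.
#'
#' @param path Path to a 6-column BED file (no header).
#' @param feature_kind "gene" or "mirna" assigned to every record, or NULL to
#'   take kinds from the score column being unused and the name prefix
#'   "mir" (case-insensitive) meaning mirna.
#' @return data.frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `feature_kind`.
#' @export
read_bed <- function(path, feature_kind = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED file needs at least 4 columns")
  ann <- data.frame(feature_id = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (is.null(feature_kind)) {
    ann$feature_kind <- ifelse(grepl("mir", ann$feature_id, ignore.case = TRUE),
                               "mirna", "gene")
  } else {
    ann$feature_kind <- feature_kind
  }
  genome_annotation(ann)
}

#' @rdname read_bed
#' @param ann A genome-annotation data.frame.
#' @export
write_bed <- function(ann, path) {
  out <- data.frame(ann$chrom, ann$start, ann$end, ann$feature_id, 0L, "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a genome annotation table
#' @param ann data.frame with feature_id, chrom, start, end, feature_kind.
#' @return The validated data.frame (class `genome_annotation`).
#' @export
genome_annotation <- function(ann) {
  stopifnot(all(c("feature_id", "chrom", "start", "end", "feature_kind")
                %in% names(ann)))
  if (any(ann$start >= ann$end)) stop("annotation record with start >= end")
  for (kind in unique(ann$feature_kind)) {
    ids <- ann$feature_id[ann$feature_kind == kind]
    if (anyDuplicated(ids)) stop("duplicate feature id within kind ", kind)
  }
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Read a multi-database miRNA-target table
#'
#' TSV with columns `miRNA`, `gene`, `database`; duplicate triples collapse
#' to one.  When a database whitelist is given, unknown database names raise
#' a warning but the rows are kept (they still vote).
#'
#' @param path Path to the targets TSV.
#' @param databases Optional character vector of expected database names.
#' @return data.frame of unique (mirna, gene, database) triples.
#' @export
read_target_db <- function(path, databases = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("miRNA", "gene", "database") %in% names(tab))) {
    stop("target file needs columns miRNA, gene, database")
  }
  trip <- unique(data.frame(mirna = as.character(tab$miRNA),
                            gene = as.character(tab$gene),
                            database = as.character(tab$database),
                            stringsAsFactors = FALSE))
  if (!is.null(databases)) {
    unknown <- setdiff(unique(trip$database), databases)
    if (length(unknown) > 0) {
      warning("unknown target database(s): ", paste(unknown, collapse = ", "),
              " (rows kept)")
    }
  }
  rownames(trip) <- NULL
  trip
}

#' @rdname read_target_db
#' @param triples data.frame of (mirna, gene, database) triples.
#' @export
write_target_db <- function(triples, path) {
  out <- data.frame(miRNA = triples$mirna, gene = triples$gene,
                    database = triples$database)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a co-expression edge list
#'
#' TSV with two gene columns plus a free-text provenance column (the shape of
#' a GeneMania co-expression export).  Edges are undirected: a pair listed in
#' both orientations collapses to one edge.  Self-loops are rejected.
#'
#' @param path Path to the edge TSV (header required; first two columns are
#'   the gene pair, third the provenance).
#' @return data.frame with columns `entity1`, `entity2`, `provenance`, one
#'   row per undirected edge.
#' @export
read_network_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge file needs at least two columns")
  e1 <- as.character(tab[[1]]); e2 <- as.character(tab[[2]])
  prov <- if (ncol(tab) >= 3) as.character(tab[[3]]) else ""
  if (any(e1 == e2)) stop("self-loop edge: ", e1[which(e1 == e2)[1]])
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(entity1 = lo[keep], entity2 = hi[keep],
                      provenance = prov[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

#' @rdname read_network_edges
#' @param edges data.frame with entity1, entity2, provenance.
#' @export
write_network_edges <- function(edges, path) {
  out <- data.frame(entity1 = edges$entity1, entity2 = edges$entity2,
                    provenance = edges$provenance)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a published gene signature (one symbol per line)
#' @param path Path to a plain-text file, one gene symbol per line; blank
#'   lines and lines starting with '#' are skipped.
#' @return Character vector of gene symbols.
#' @export
read_signature <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
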