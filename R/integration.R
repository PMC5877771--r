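#' Direction-concordant intersection of expression and copy-number calls
#'
#' Upregulated genes with copy-number gains, and downregulated genes with
#' copy-number losses; discordant combinations are excluded.
#'
#' @param up,down Character vectors of up-/down-regulated gene ids.
#' @param amplified,deleted Character vectors of amplified/deleted gene ids.
#' @return List with `up_amplified` and `down_deleted` gene vectors.
#' @export
intersect_expression_cna <- function(up, down, amplified, deleted) {
  list(up_amplified = sort(intersect(up, amplified)),
       down_deleted = sort(intersect(down, deleted)))
}

#' Direction-crossed intersection of copy-number calls and miRNA targets
#'
#' Amplified genes that are consensus targets of downregulated miRNAs, and
#' deleted genes that are targets of upregulated miRNAs (an upregulated
#' miRNA represses its target, so a suppressed, deleted gene pairs with an
#' up-miRNA and vice versa).
#'
#' @param amplified,deleted Gene id vectors.
#' @param cons A `consensus_targets` object.
#' @param up_mirnas,down_mirnas miRNA id vectors by expression direction.
#' @return List with `amplified_target_of_down` and `deleted_target_of_up`.
#' @export
intersect_cna_targets <- function(amplified, deleted, cons,
                                  up_mirnas, down_mirnas) {
  list(amplified_target_of_down =
         sort(intersect(amplified, targets_of(cons, down_mirnas))),
       deleted_target_of_up =
         sort(intersect(deleted, targets_of(cons, up_mirnas))))
}

#' Direction-crossed intersection of expression calls and miRNA targets
#'
#' @param up,down Gene id vectors by expression direction.
#' @inheritParams intersect_cna_targets
#' @return List with `up_target_of_down` and `down_target_of_up`.
#' @export
intersect_expression_targets <- function(up, down, cons,
                                         up_mirnas, down_mirnas) {
  list(up_target_of_down = sort(intersect(up, targets_of(cons, down_mirnas))),
       down_target_of_up = sort(intersect(down, targets_of(cons, up_mirnas))))
}

#' Nominate core genes
#'
#' A core gene lies in the direction-consistent expression-CNA intersection
#' and is a consensus target of at least one oppositely deregulated miRNA:
#' upregulated-and-amplified genes targeted by down-miRNAs, and
#' downregulated-and-deleted genes targeted by up-miRNAs.  Each record lists
#' exactly the direction-opposed regulating miRNAs.
#'
#' @param up_amplified,down_deleted Gene vectors from
#'   [intersect_expression_cna()].
#' @param cons A `consensus_targets` object.
#' @param up_mirnas,down_mirnas Deregulated miRNA ids by direction; a miRNA
#'   appearing in both sets aborts with a validation error.
#' @return data.frame with columns `gene_id`, `direction` (up/down), `cna`
#'   (amplified/deleted), `regulating_mirnas` (comma-joined ids).
#' @export
core_genes <- function(up_amplified, down_deleted, cons,
                       up_mirnas, down_mirnas) {
  clash <- intersect(up_mirnas, down_mirnas)
  if (length(clash) > 0) {
    stop("miRNA(s) present in both direction sets: ",
         paste(clash, collapse = ", "))
  }
  one_branch <- function(genes, direction, cna, opposing) {
    recs <- lapply(genes, function(g) {
      regs <- intersect(regulators_of(cons, g), opposing)
      if (length(regs) == 0) return(NULL)
      data.frame(gene_id = g, direction = direction, cna = cna,
                 regulating_mirnas = paste(regs, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  }
  out <- rbind(one_branch(up_amplified, "up", "amplified", down_mirnas),
               one_branch(down_deleted, "down", "deleted", up_mirnas))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), direction = character(),
                      cna = character(), regulating_mirnas = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Venn accounting of the three evidence layers
#'
#' Region counts of the three-set diagram (differential expression,
#' copy-number alteration, miRNA targeting) for one direction branch.
#'
#' @param de,cna,target Character vectors (gene sets for one direction
#'   branch: e.g. up genes, amplified genes, targets of down-miRNAs).
#' @return Named integer vector over the 7 regions
#'   (de_only, cna_only, target_only, de_cna, de_target, cna_target,
#'   de_cna_target).
#' @export
venn_summary <- function(de, cna, target) {
  universe <- unique(c(de, cna, target))
  in_de <- universe %in% de
  in_cna <- universe %in% cna
  in_tg <- universe %in% target
  c(de_only = sum(in_de & !in_cna & !in_tg),
    cna_only = sum(!in_de & in_cna & !in_tg),
    target_only = sum(!in_de & !in_cna & in_tg),
    de_cna = sum(in_de & in_cna & !in_tg),
    de_target = sum(in_de & !in_cna & in_tg),
    cna_target = sum(!in_de & in_cna & in_tg),
    de_cna_target = sum(in_de & in_cna & in_tg))
}

#' Overlap of core genes with published signatures
#'
#' Genes present in the core set and in at least one supplied signature
#' file, annotated with the signature(s) containing them.  Symbols are
#' matched case-insensitively.
#'
#' @param core Character vector of core gene ids.
#' @param signature_files Character vector of file paths (one gene symbol
#'   per line); names are used as signature labels, else base names.
#' @return data.frame `gene_id`, `signatures` (comma-joined labels).
#' @export
signature_overlap <- function(core, signature_files) {
  if (length(signature_files) == 0) {
    return(data.frame(gene_id = character(), signatures = character(),
                      stringsAsFactors = FALSE))
  }
  labels <- names(signature_files)
  if (is.null(labels)) labels <- rep(NA_character_, length(signature_files))
  labels <- ifelse(is.na(labels) | labels == "",
                   sub("\\.[^.]*$", "", basename(signature_files)), labels)
  hits <- list()
  for (i in seq_along(signature_files)) {
    sig <- toupper(read_signature(signature_files[[i]]))
    found <- core[toupper(core) %in% sig]
    for (g in found) hits[[g]] <- c(hits[[g]], labels[i])
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id = character(), signatures = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene_id = names(hits),
                    signatures = vapply(hits, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
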