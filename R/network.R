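#' Gene set of a co-expression network
#'
#' @param edges Edge data.frame from [read_network_edges()].
#' @return Sorted character vector: union of both entity columns.
#' @export
network_gene_set <- function(edges) {
  sort(unique(c(edges$entity1, edges$entity2)))
}

#' Fisher-exact enrichment of miRNA targets in a network
#'
#' For every miRNA with at least one consensus target inside the universe,
#' tests whether its targets are over-represented among the network genes:
#' with N universe genes, K of them in the network, n targets of the miRNA
#' in the universe, and k targeted network genes, the one-sided p-value is
#' the hypergeometric upper tail Pr(X >= k).  A miRNA is enriched when
#' p < `alpha`.
#'
#' @param cons A `consensus_targets` object.
#' @param network_genes Character vector (must be a subset of `universe`).
#' @param universe Character vector: the background gene set.
#' @param alpha Enrichment threshold on the raw p-value.
#' @param adjust Apply BH across tested miRNAs before thresholding
#'   (default FALSE: the raw-p rule).
#' @return data.frame mirna_id, k, K, n, N, p_value, enriched.
#' @export
fisher_enrichment <- function(cons, network_genes, universe,
                              alpha = 0.05, adjust = FALSE) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (!all(network_genes %in% universe)) {
    stop("network genes must be contained in the universe")
  }
  N <- length(universe)
  K <- length(unique(network_genes))
  recs <- lapply(names(cons$forward), function(m) {
    tg <- intersect(cons$forward[[m]], universe)
    n <- length(tg)
    if (n == 0) return(NULL)
    k <- length(intersect(tg, network_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(mirna_id = m, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  p_eff <- if (adjust && nrow(out) > 0) bh_adjust(out$p_value) else out$p_value
  out$enriched <- p_eff < alpha
  rownames(out) <- NULL
  out
}

#' Rank master-regulator miRNA candidates
#'
#' Enriched miRNAs sorted by ascending p-value, ties broken by descending
#' number of targeted network genes then lexically by miRNA id; the first
#' element is the master-regulator candidate.
#'
#' @param records Output of [fisher_enrichment()].
#' @return The enriched subset, ordered.
#' @export
rank_master_mirnas <- function(records) {
  enr <- records[records$enriched, , drop = FALSE]
  if (nrow(enr) == 0) return(enr)
  ord <- order(enr$p_value, -enr$k, enr$mirna_id)
  out <- enr[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
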