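#' The ten miRNA-target prediction databases of the consensus universe
#' @export
TARGET_DATABASES <- c("DIANA-mT", "miRanda", "miRDB", "miRWalk", "RNAhybrid",
                      "PICTAR4", "PICTAR5", "PITA", "RNA22", "TargetScan")

#' Consensus miRNA-target sets by database voting
#'
#' A miRNA-gene pair is a consensus target when it is predicted by at least
#' `min_votes` distinct databases.  Duplicate predictions from the same
#' database count once.
#'
#' @param triples data.frame of (mirna, gene, database) triples, e.g. from
#'   [read_target_db()].
#' @param min_votes Minimum number of distinct databases.
#' @return Object of class `consensus_targets`: list with `forward`
#'   (mirna -> character vector of genes), `reverse` (gene -> miRNAs) and
#'   `pairs` (data.frame mirna, gene, votes).
#' @export
consensus <- function(triples, min_votes = 5L) {
  trip <- unique(triples[, c("mirna", "gene", "database")])
  key <- paste(trip$mirna, trip$gene, sep = "\r")
  votes <- table(key)
  keep_keys <- names(votes)[votes >= min_votes]
  idx <- !duplicated(key) & key %in% keep_keys
  pairs <- data.frame(mirna = trip$mirna[idx], gene = trip$gene[idx],
                      votes = as.integer(votes[key[idx]]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  obj <- list(
    forward = split(pairs$gene, pairs$mirna),
    reverse = split(pairs$mirna, pairs$gene),
    pairs = pairs
  )
  class(obj) <- "consensus_targets"
  obj
}

#' @export
print.consensus_targets <- function(x, ...) {
  cat(sprintf("consensus_targets: %d pairs, %d miRNAs, %d genes\n",
              nrow(x$pairs), length(x$forward), length(x$reverse)))
  invisible(x)
}

#' Union of consensus targets over a miRNA set
#'
#' @param cons A `consensus_targets` object.
#' @param mirnas Character vector of miRNA ids (absent ids contribute
#'   nothing).
#' @return Character vector: the union of the miRNAs' target gene sets.
#' @export
targets_of <- function(cons, mirnas) {
  stopifnot(inherits(cons, "consensus_targets"))
  if (length(mirnas) == 0) return(character())
  sort(unique(unlist(cons$forward[intersect(mirnas, names(cons$forward))],
                     use.names = FALSE)))
}

#' miRNAs among the consensus regulators of a gene
#' @param cons A `consensus_targets` object.
#' @param gene Gene id.
#' @return Character vector of miRNA ids targeting the gene.
#' @export
regulators_of <- function(cons, gene) {
  stopifnot(inherits(cons, "consensus_targets"))
  mir <- cons$reverse[[gene]]
  if (is.null(mir)) character() else sort(unique(mir))
}
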