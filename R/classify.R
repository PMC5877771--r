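#' Feature matrix for one evaluation approach
#'
#' Restricts a log2(count + 1)-transformed expression matrix to the feature
#' set of one of the evaluation approaches (I: all differentially expressed
#' genes; II: expression-CNA intersection; III: core genes; IV: the
#' published-signature overlap; V: the co-expression network genes; VI: the
#' master miRNA, drawn from the miRNA matrix).
#'
#' @param features Character vector of feature ids (genes, or miRNAs for
#'   approach VI).
#' @param expr A `count_matrix` holding those features.
#' @return Numeric samples x features matrix of log2(count + 1) values.
#' @export
build_feature_matrix <- function(features, expr) {
  stopifnot(inherits(expr, "count_matrix"))
  if (length(features) == 0) stop("empty feature set")
  missing <- setdiff(features, rownames(expr$counts))
  if (length(missing) > 0) {
    stop("features absent from matrix: ", paste(missing, collapse = ", "))
  }
  t(log2(expr$counts[features, , drop = FALSE] + 1))
}

#' Rank-statistic AUC
#'
#' Probability that a random tumor sample's score outranks a random normal
#' sample's, ties credited 0.5 (the Mann-Whitney construction).
#'
#' @param scores Numeric classifier scores (higher = more tumor-like).
#' @param labels Character vector of "tumor"/"normal" aligned with scores.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  pos <- scores[labels == "tumor"]
  neg <- scores[labels == "normal"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# stratified k-fold assignment: each class split evenly across folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer samples than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated AUC of a feature set under balanced resampling
#'
#' For each balanced resample of the cohort, runs stratified k-fold
#' cross-validation of a random-forest classifier (class-probability votes
#' as scores), pools the out-of-fold scores, and computes the AUC by the
#' rank statistic.  The report carries one AUC per resample and their mean.
#'
#' @param feature_matrix Samples x features numeric matrix (e.g. from
#'   [build_feature_matrix()]).
#' @param labels Named character vector sample -> tumor/normal covering the
#'   matrix rows.
#' @param config An `analysis_config` (cv_folds, n_resamples, n_trees,
#'   rng_seed).
#' @param approach_id Free-text label stored in the report.
#' @return List of class `classification_report`: approach_id, feature_ids,
#'   auc_per_run, auc_mean.
#' @export
cv_auc <- function(feature_matrix, labels, config = analysis_config(),
                   approach_id = "custom") {
  labels <- labels[rownames(feature_matrix)]
  stopifnot(!anyNA(labels), all(labels %in% c("tumor", "normal")))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  subsets <- balanced_resample_indices(labels, config$n_resamples,
                                       config$rng_seed)
  set.seed(config$rng_seed + 1L)
  aucs <- vapply(seq_along(subsets), function(r) {
    ids <- subsets[[r]]
    xm <- feature_matrix[ids, , drop = FALSE]
    y <- factor(labels[ids], levels = c("normal", "tumor"))
    fold <- stratified_folds(as.character(y), config$cv_folds)
    scores <- numeric(length(y))
    for (f in seq_len(config$cv_folds)) {
      train <- fold != f
      tr_x <- xm[train, , drop = FALSE]
      # features constant on the training fold carry no signal and stall
      # the forest; with nothing left the fold scores are uninformative
      keep_f <- apply(tr_x, 2, function(v) any(v != v[1]))
      if (!any(keep_f)) {
        scores[!train] <- 0.5
        next
      }
      fit <- randomForest::randomForest(
        x = tr_x[, keep_f, drop = FALSE], y = y[train],
        ntree = config$n_trees)
      scores[!train] <- stats::predict(fit, xm[!train, keep_f, drop = FALSE],
                                       type = "prob")[, "tumor"]
    }
    auc_rank(scores, as.character(y))
  }, numeric(1))
  report <- list(approach_id = approach_id,
                 feature_ids = colnames(feature_matrix),
                 auc_per_run = aucs,
                 auc_mean = mean(aucs))
  class(report) <- "classification_report"
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report [%s]: %d features, mean AUC %.3f (%s)\n",
              x$approach_id, length(x$feature_ids), x$auc_mean,
              paste(sprintf("%.2f", x$auc_per_run), collapse = ", ")))
  invisible(x)
}

#' Random-gene baseline for a signature of a given size
#'
#' Draws `n_draws` uniform random feature subsets of size `n_features`
#' (without replacement) and evaluates each with [cv_auc()], yielding the
#' AUC distribution a matched-size random signature achieves.
#'
#' @param n_features Subset size.
#' @param n_draws Number of random subsets.
#' @param expr A `count_matrix` to draw features from.
#' @param labels Named class vector.
#' @param config An `analysis_config`.
#' @param seed Seed for the subset draws.
#' @return List of `classification_report`s (approach_id "random:<size>").
#' @export
random_gene_baseline <- function(n_features, n_draws, expr, labels,
                                 config = analysis_config(), seed = 1L) {
  pool <- rownames(expr$counts)
  stopifnot(n_features <= length(pool))
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) sample(pool, n_features))
  lapply(draws, function(fs) {
    cv_auc(build_feature_matrix(fs, expr), labels, config,
           approach_id = paste0("random:", n_features))
  })
}

#' Cross-validated AUC of a single feature
#'
#' @param gene Feature id.
#' @param expr A `count_matrix`.
#' @param labels Named class vector.
#' @param config An `analysis_config`.
#' @return A `classification_report` (approach_id "single:<gene>").
#' @export
single_gene_auc <- function(gene, expr, labels, config = analysis_config()) {
  cv_auc(build_feature_matrix(gene, expr), labels, config,
         approach_id = paste0("single:", gene))
}
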