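#' Analysis configuration
#'
#' Bundles every threshold of the integrative pipeline in one validated
#' object.  Defaults follow the published parameterization of each stage:
#' quantile expression filter at the 25th percentile of feature means,
#' differential-expression calls at |log2 FC| > 1 and FDR < 0.01, GISTIC-style
#' copy-number thresholds at +/-0.1 log2 ratio with sub-4-marker segment
#' joining and q < 0.25, target consensus at >= 5 of 10 databases, network
#' enrichment at Fisher p < 0.05, and evaluation by 10-fold cross-validation
#' over 7 balanced resamples.
#'
#' @param quantile_cut Fraction in (0,1); quantile of feature means below
#'   which features are filtered out.
#' @param lfc_threshold Non-negative log2 fold-change threshold for calling a
#'   feature up/down.
#' @param fdr_threshold FDR threshold (fraction in (0,1)) for calling a
#'   feature differentially expressed.
#' @param cna_gain_threshold Log2 copy-ratio above which a sample contributes
#'   to a gene's amplification score.
#' @param cna_loss_threshold Log2 copy-ratio below which a sample contributes
#'   to a gene's deletion score (negative).
#' @param min_markers Segments with fewer markers are joined to the
#'   neighboring segment closest in copy number.
#' @param cna_q_threshold q-value threshold for significant amplification /
#'   deletion calls.
#' @param consensus_min_votes Minimum number of distinct databases that must
#'   predict a miRNA-gene pair for it to be a consensus target.
#' @param consensus_n_databases Size of the database universe.
#' @param fisher_alpha p-value threshold for network enrichment.
#' @param cv_folds Number of cross-validation folds.
#' @param n_resamples Number of balanced resamples (class-balanced subsets).
#' @param resample_combine How differential-expression calls are combined
#'   across resamples: a feature must be called in all resamples
#'   ("intersection", default), in any ("union"), or in more than half
#'   ("majority").
#' @param n_trees Number of trees in the random-forest classifier.
#' @param n_perm Number of permutations for the copy-number null model.
#' @param rng_seed Integer seed driving every stochastic step.
#' @return An object of class \code{analysis_config} (a validated list).
#' @export
analysis_config <- function(quantile_cut = 0.25,
                            lfc_threshold = 1.0,
                            fdr_threshold = 0.01,
                            cna_gain_threshold = 0.1,
                            cna_loss_threshold = -0.1,
                            min_markers = 4L,
                            cna_q_threshold = 0.25,
                            consensus_min_votes = 5L,
                            consensus_n_databases = 10L,
                            fisher_alpha = 0.05,
                            cv_folds = 10L,
                            n_resamples = 7L,
                            resample_combine = c("intersection", "union", "majority"),
                            n_trees = 500L,
                            n_perm = 200L,
                            rng_seed = 1L) {
  resample_combine <- match.arg(resample_combine)
  cfg <- list(
    quantile_cut = quantile_cut,
    lfc_threshold = lfc_threshold,
    fdr_threshold = fdr_threshold,
    cna_gain_threshold = cna_gain_threshold,
    cna_loss_threshold = cna_loss_threshold,
    min_markers = as.integer(min_markers),
    cna_q_threshold = cna_q_threshold,
    consensus_min_votes = as.integer(consensus_min_votes),
    consensus_n_databases = as.integer(consensus_n_databases),
    fisher_alpha = fisher_alpha,
    cv_folds = as.integer(cv_folds),
    n_resamples = as.integer(n_resamples),
    resample_combine = resample_combine,
    n_trees = as.integer(n_trees),
    n_perm = as.integer(n_perm),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  frac <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x < 1
  stopifnot(
    "quantile_cut must be in (0,1)" = frac(cfg$quantile_cut) || cfg$quantile_cut == 0,
    "fdr_threshold must be in (0,1)" = frac(cfg$fdr_threshold),
    "cna_q_threshold must be in (0,1)" = frac(cfg$cna_q_threshold),
    "fisher_alpha must be in (0,1)" = frac(cfg$fisher_alpha),
    "lfc_threshold must be >= 0" = cfg$lfc_threshold >= 0,
    "cna_gain_threshold must be > 0" = cfg$cna_gain_threshold > 0,
    "cna_loss_threshold must be < 0" = cfg$cna_loss_threshold < 0,
    "min_markers must be >= 1" = cfg$min_markers >= 1L,
    "consensus_min_votes must not exceed consensus_n_databases" =
      cfg$consensus_min_votes <= cfg$consensus_n_databases,
    "consensus_min_votes must be >= 1" = cfg$consensus_min_votes >= 1L,
    "cv_folds must be >= 2" = cfg$cv_folds >= 2L,
    "n_resamples must be >= 1" = cfg$n_resamples >= 1L,
    "n_trees must be >= 1" = cfg$n_trees >= 1L
  )
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' The on-disk file mirrors the field names of [analysis_config()]; absent
#' fields fall back to the defaults, unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
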