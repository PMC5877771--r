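#' Quantile filter on feature means
#'
#' Removes weakly expressed features before testing: each feature's mean
#' count across all samples is computed, the threshold is the empirical
#' quantile (linear interpolation) of those means at `quantile_cut`, and
#' features with mean strictly greater than the threshold are retained.
#'
#' @param x A `count_matrix`.
#' @param quantile_cut Fraction; quantile of feature means used as threshold.
#' @return A `count_matrix` restricted to the retained features.
#' @export
quantile_filter <- function(x, quantile_cut = 0.25) {
  stopifnot(inherits(x, "count_matrix"), nrow(x$counts) > 0)
  means <- rowMeans(x$counts)
  thr <- stats::quantile(means, quantile_cut, names = FALSE, type = 7)
  keep <- means > thr
  if (!any(keep)) {
    warning("quantile filter removed every feature (identical means?)")
    y <- x
    y$counts <- x$counts[keep, , drop = FALSE]
    return(y)
  }
  y <- x
  y$counts <- x$counts[keep, , drop = FALSE]
  y
}

#' Equalize library sizes by scaling to the geometric mean
#'
#' Rescales every sample's counts so that all library sizes match the
#' geometric mean of the observed library sizes, rounding to the nearest
#' integer.  This is the pseudo-count step that puts samples on a common
#' footing before conditional-likelihood dispersion estimation and exact
#' testing.
#'
#' @param x A `count_matrix` with positive library sizes.
#' @return A `count_matrix` of pseudo-counts.
#' @export
equalize_libraries <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- colSums(x$counts)
  if (any(lib <= 0)) stop("sample with zero library size")
  target <- exp(mean(log(lib)))
  pseudo <- round(sweep(x$counts, 2, target / lib, `*`))
  storage.mode(pseudo) <- "integer"
  y <- x
  y$counts <- pseudo
  y
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' With equalized library sizes, each feature's counts within a class are
#' modeled as i.i.d. NB(mu, phi) with variance mu + phi * mu^2.  Conditioning
#' on each class's total removes the mean and leaves a likelihood in phi
#' alone; the per-feature, per-class conditional log-likelihoods are summed
#' and maximized over a log-spaced grid on [1e-6, 10] followed by
#' golden-section refinement.
#'
#' @param pseudo A `count_matrix` of equalized pseudo-counts.
#' @param classes Optional named class vector (defaults to the matrix's own).
#' @return List with `phi`, `log_conditional_likelihood`, `n_features_used`.
#' @export
estimate_common_dispersion <- function(pseudo, classes = NULL) {
  stopifnot(inherits(pseudo, "count_matrix"))
  if (is.null(classes)) classes <- pseudo$sample_class
  counts <- pseudo$counts
  groups <- split(seq_len(ncol(counts)), classes)
  if (any(lengths(groups) < 2)) stop("need >= 2 samples per class")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("no non-zero features")

  # summed conditional NB log-likelihood at dispersion phi (r = 1/phi)
  cll <- function(phi) {
    r <- 1 / phi
    total <- 0
    for (idx in groups) {
      y <- counts[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      total <- total +
        sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
        nrow(y) * lgamma(n * r) - sum(lgamma(z + n * r))
    }
    total
  }
  grid <- exp(seq(log(1e-6), log(10), length.out = 25))
  vals <- vapply(grid, cll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(cll, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  # boundary wins if refinement does not beat the grid edge
  phi <- opt$maximum
  ll <- opt$objective
  if (vals[i] > ll) {
    phi <- grid[i]
    ll <- vals[i]
  }
  list(phi = phi, log_conditional_likelihood = ll,
       n_features_used = nrow(counts))
}

#' Exact negative-binomial two-group test for one feature
#'
#' Assumes equalized library sizes.  Conditional on the feature's total
#' count t, the class-1 sum A follows the distribution of a sum of n1 i.i.d.
#' NB(mu, phi) variables given that the overall sum is t; since a sum of n
#' i.i.d. NB(mu, phi) variables is NB with size n/phi and mean n*mu, the
#' conditional law is computed exactly over the support 0..t.  The two-sided
#' p-value adds the probability of every outcome no more likely than the
#' observed one; at phi = 0 the Poisson limit (a binomial conditional law)
#' is used.
#'
#' @param counts1,counts2 Integer count vectors for the two classes.
#' @param phi Common NB dispersion (>= 0).
#' @return Two-sided p-value in (0, 1].
#' @export
exact_nb_test <- function(counts1, counts2, phi) {
  n1 <- length(counts1); n2 <- length(counts2)
  stopifnot(n1 >= 1, n2 >= 1, phi >= 0)
  a_obs <- sum(counts1)
  t <- a_obs + sum(counts2)
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  a <- 0:t
  if (phi > 0) {
    logf <- stats::dnbinom(a, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(t - a, size = n2 / phi, mu = n2 * mu, log = TRUE)
  } else {
    logf <- stats::dpois(a, n1 * mu, log = TRUE) +
      stats::dpois(t - a, n2 * mu, log = TRUE)
  }
  logf <- logf - max(logf)
  p_a <- exp(logf)
  p_a <- p_a / sum(p_a)
  p_obs <- p_a[a_obs + 1L]
  # outcomes no more likely than the observed one, with a relative
  # tolerance so exact ties survive floating-point evaluation order
  min(1, sum(p_a[p_a <= p_obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control returned in input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values (FDR) in [0, 1].
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Balanced resampling of an unbalanced two-class cohort
#'
#' Each resample keeps every member of the minority class and draws, without
#' replacement, an equal number of samples from the majority class, so each
#' resample is class-balanced.
#'
#' @param sample_class Named character vector (sample id -> class).
#' @param n_resamples Number of resamples.
#' @param seed Integer seed.
#' @return List of character vectors of sample ids.
#' @export
balanced_resample_indices <- function(sample_class, n_resamples, seed) {
  classes <- split(names(sample_class), sample_class)
  if (length(classes) != 2 || any(lengths(classes) == 0)) {
    stop("need two non-empty classes")
  }
  sizes <- lengths(classes)
  i_min <- which.min(sizes)
  minority <- classes[[i_min]]
  majority <- classes[[-i_min]]
  k <- length(minority)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(
    lapply(seq_len(n_resamples), function(i) {
      drawn <- if (length(majority) == k) majority else sample(majority, k)
      ids <- c(minority, drawn)
      ids[order(match(ids, names(sample_class)))]
    })
  )
}

#' Call differentially expressed features with balanced resampling
#'
#' For each balanced resample the libraries are equalized, a common NB
#' dispersion is estimated by conditional maximum likelihood, every feature
#' gets an exact NB p-value, BH adjustment is applied, and features are
#' called up (log2 FC > `lfc_threshold` and FDR < `fdr_threshold`) or down
#' (mirrored).  The final up/down sets combine the per-resample calls by the
#' configured rule (intersection by default: a feature must be called in
#' every resample).  Reported log2 FC / p / FDR come from the first resample.
#'
#' @param x A filtered `count_matrix`.
#' @param config An `analysis_config`.
#' @return List with `up`, `down` (character vectors), `table` (one
#'   `DERecord` row per feature: feature_id, log_fc, p_value, fdr, status)
#'   and `dispersion` (first-resample estimate).
#' @export
call_degs <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "count_matrix"))
  idx_sets <- balanced_resample_indices(x$sample_class, config$n_resamples,
                                        config$rng_seed)
  per_up <- vector("list", length(idx_sets))
  per_down <- vector("list", length(idx_sets))
  first <- NULL
  disp1 <- NULL
  for (r in seq_along(idx_sets)) {
    sub <- subset_samples(x, idx_sets[[r]])
    pseudo <- equalize_libraries(sub)
    disp <- estimate_common_dispersion(pseudo)
    cls <- pseudo$sample_class
    tum <- cls == "tumor"; nor <- cls == "normal"
    counts <- pseudo$counts
    pv <- vapply(seq_len(nrow(counts)), function(i) {
      exact_nb_test(counts[i, tum], counts[i, nor], disp$phi)
    }, numeric(1))
    fdr <- bh_adjust(pv)
    lfc <- log2((rowMeans(counts[, tum, drop = FALSE]) + 0.5) /
                (rowMeans(counts[, nor, drop = FALSE]) + 0.5))
    up <- lfc > config$lfc_threshold & fdr < config$fdr_threshold
    down <- lfc < -config$lfc_threshold & fdr < config$fdr_threshold
    per_up[[r]] <- rownames(counts)[up]
    per_down[[r]] <- rownames(counts)[down]
    if (r == 1L) {
      first <- data.frame(feature_id = rownames(counts), log_fc = unname(lfc),
                          p_value = pv, fdr = fdr,
                          stringsAsFactors = FALSE)
      disp1 <- disp
    }
  }
  combine <- function(sets) {
    switch(config$resample_combine,
           intersection = Reduce(intersect, sets),
           union = Reduce(union, sets),
           majority = {
             tab <- table(unlist(sets))
             names(tab)[tab > length(sets) / 2]
           })
  }
  up <- combine(per_up)
  down <- combine(per_down)
  down <- setdiff(down, up)  # exclusivity guard; cannot trigger by construction
  first$status <- ifelse(first$feature_id %in% up, "up",
                         ifelse(first$feature_id %in% down, "down",
                                "not_significant"))
  rownames(first) <- NULL
  list(up = up, down = down, table = first, dispersion = disp1)
}
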