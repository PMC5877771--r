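# shared small designs and lazily cached cohorts for the unit tests

small_design <- function(seed = 7L, ...) {
  args <- list(n_tumor = 12L, n_normal = 12L,
               n_genes = 300L, n_mirnas = 40L,
               n_core_up = 6L, n_core_down = 6L,
               n_decoys_per_layer = 3L,
               n_up_mirnas = 8L, n_down_mirnas = 8L,
               n_network_genes = 10L, n_overlap_genes = 3L,
               rng_seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_design, args)
}

fast_config <- function(seed = 7L, ...) {
  args <- list(n_resamples = 3L, cv_folds = 5L, n_trees = 100L,
               n_perm = 50L, rng_seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(analysis_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cohort <- function() cached("small_cohort", generate_cohort(small_design()))

# random labeled count matrix for IO round-trips
random_count_matrix <- function(n_feat = 50L, n_samp = 20L, seed = 1L) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_feat * n_samp, mu = 50, size = 5),
                   n_feat, n_samp,
                   dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                                   sprintf("S%03d", seq_len(n_samp))))
  cls <- setNames(rep(c("tumor", "normal"), length.out = n_samp),
                  colnames(counts))
  count_matrix(counts, cls)
}

# exhaustive conditional-distribution oracle for the exact NB test: builds
# the pmf of each class sum by explicit convolution of per-sample NB pmfs,
# then forms the conditional law of the class-1 sum given the total
enumerate_exact_nb <- function(counts1, counts2, phi) {
  t <- sum(counts1) + sum(counts2)
  mu <- t / (length(counts1) + length(counts2))
  pmf1 <- function(n) {
    # convolution of n i.i.d. NB(mu, phi) pmfs truncated to 0..t
    base <- if (phi > 0) dnbinom(0:t, size = 1 / phi, mu = mu) else dpois(0:t, mu)
    out <- base
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        out <- convolve(out, rev(base), type = "open")[1:(t + 1)]
      }
    }
    out
  }
  f1 <- pmf1(length(counts1))
  f2 <- pmf1(length(counts2))
  joint <- f1 * rev(f2)          # Pr(A = a) Pr(B = t - a), a = 0..t
  cond <- joint / sum(joint)
  p_obs <- cond[sum(counts1) + 1L]
  min(1, sum(cond[cond <= p_obs * (1 + 1e-9)]))
}

# exhaustive hypergeometric tail by enumerating every C(N, n) draw
enumerate_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_K <- draws <= K             # label items 1..K as the "network" items
  mean(colSums(in_K) >= k)
}
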