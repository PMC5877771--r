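make_cm <- function(counts) {
  counts <- as.matrix(counts)
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  cls <- setNames(rep(c("tumor", "normal"), length.out = ncol(counts)),
                  colnames(counts))
  count_matrix(counts, cls)
}

test_that("quantile filter thresholds at the interpolated quantile of feature means", {
  cm <- make_cm(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  kept <- quantile_filter(cm, 0.25)
  # threshold = 25th percentile of (1,2,3,4) = 1.75; means 2,3,4 survive
  expect_equal(nrow(kept$counts), 3L)
  expect_true(all(rowMeans(kept$counts) > 1.75))
  # cut 0: everything above the minimum mean survives
  kept0 <- quantile_filter(cm, 0)
  expect_equal(nrow(kept0$counts), 3L)
  # identical means: everything filtered, with a warning
  flat <- make_cm(cbind(c(5, 5), c(5, 5)))
  expect_warning(none <- quantile_filter(flat, 0.25), "every feature")
  expect_equal(nrow(none$counts), 0L)
})

test_that("library equalization rescales to the geometric mean", {
  cm <- make_cm(cbind(c(60, 40), c(240, 160)))  # libraries 100 and 400
  eq <- equalize_libraries(cm)
  expect_equal(unname(colSums(eq$counts)), c(200, 200))
  expect_true(all(eq$counts >= 0))
  # equal libraries: identity
  cm2 <- make_cm(cbind(c(60, 40), c(70, 30)))
  expect_identical(equalize_libraries(cm2)$counts, cm2$counts)
  # zero library is an error
  cm3 <- make_cm(cbind(c(0, 0), c(10, 5)))
  expect_error(equalize_libraries(cm3), "zero library")
})

test_that("common dispersion is recovered by conditional maximum likelihood", {
  sim <- function(phi, n_feat = 2000L, n_samp = 20L, seed = 11L) {
    set.seed(seed)
    mu <- exp(runif(n_feat, log(20), log(200)))
    counts <- matrix(0L, n_feat, n_samp)
    for (j in seq_len(n_samp)) {
      counts[, j] <- if (phi > 0) rnbinom(n_feat, size = 1 / phi, mu = mu)
      else rpois(n_feat, mu)
    }
    make_cm(counts)
  }
  est0 <- estimate_common_dispersion(sim(0))
  expect_lte(est0$phi, 0.01)
  est3 <- estimate_common_dispersion(sim(0.3))
  expect_gte(est3$phi, 0.2)
  expect_lte(est3$phi, 0.4)
  # a single flat feature carries no overdispersion evidence
  flat <- make_cm(matrix(7L, 1, 6))
  expect_lte(estimate_common_dispersion(flat)$phi, 2e-6)
})

test_that("dispersion estimate agrees with an established qCML implementation", {
  set.seed(21)
  mu <- exp(runif(500, log(20), log(200)))
  counts <- sapply(1:12, function(j) rnbinom(500, size = 1 / 0.2, mu = mu))
  cm <- make_cm(counts)
  ours <- estimate_common_dispersion(cm)$phi
  dge <- edgeR::DGEList(counts = cm$counts,
                        group = factor(cm$sample_class))
  theirs <- edgeR::estimateCommonDisp(dge)$common.dispersion
  expect_lt(abs(ours - theirs) / theirs, 0.25)
})

test_that("exact NB test matches exhaustive conditional enumeration", {
  cases <- list(
    list(c1 = c(3L, 5L), c2 = c(9L, 11L), phi = 0.5),
    list(c1 = c(0L, 2L, 1L), c2 = c(8L, 6L), phi = 0.2),
    list(c1 = c(10L, 12L), c2 = c(11L, 9L), phi = 1.0),
    list(c1 = c(1L, 0L), c2 = c(20L, 15L), phi = 0.05)
  )
  for (cs in cases) {
    expect_equal(exact_nb_test(cs$c1, cs$c2, cs$phi),
                 enumerate_exact_nb(cs$c1, cs$c2, cs$phi),
                 tolerance = 1e-8)
  }
})

test_that("exact NB test reduces to the binomial probability-mass rule at phi = 0", {
  # one sample per class: conditional law of (k, t - k) is Binomial(t, 1/2)
  for (tk in list(c(2L, 10L), c(0L, 7L), c(6L, 6L), c(9L, 3L))) {
    k <- tk[1]; t <- sum(tk)
    pmf <- dbinom(0:t, t, 0.5)
    p_oracle <- sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-12)])
    expect_equal(exact_nb_test(tk[1], tk[2], 0), p_oracle, tolerance = 1e-10)
  }
})

test_that("exact NB test is symmetric and exchangeable", {
  expect_equal(exact_nb_test(c(4L, 6L), c(6L, 4L), 0.3), 1)
  set.seed(5)
  for (i in 1:10) {
    c1 <- rnbinom(3, size = 5, mu = 30)
    c2 <- rnbinom(3, size = 5, mu = 30)
    expect_equal(exact_nb_test(c1, c2, 0.2), exact_nb_test(c2, c1, 0.2),
                 tolerance = 1e-12)
  }
  expect_equal(exact_nb_test(c(0L, 0L), c(0L, 0L), 0.1), 1)
})

test_that("null exact-NB p-values are stochastically at least uniform", {
  set.seed(31)
  mu <- exp(runif(2000, log(20), log(150)))
  p <- vapply(seq_along(mu), function(i) {
    exact_nb_test(rnbinom(5, size = 10, mu = mu[i]),
                  rnbinom(5, size = 10, mu = mu[i]), 0.1)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH adjustment matches hand arithmetic and its contracts", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(50)
  fdr <- bh_adjust(p)
  expect_true(all(fdr <= 1))
  expect_true(all(diff(fdr[order(p)]) >= -1e-12))
})

test_that("balanced resampling keeps the minority class and balances the majority", {
  cls <- setNames(rep(c("tumor", "normal"), c(30, 8)),
                  sprintf("s%02d", 1:38))
  subs <- balanced_resample_indices(cls, 5L, seed = 4L)
  expect_length(subs, 5L)
  for (ids in subs) {
    expect_length(ids, 16L)
    expect_equal(sum(cls[ids] == "normal"), 8L)
    expect_equal(sum(cls[ids] == "tumor"), 8L)
    expect_false(anyDuplicated(ids) > 0)
  }
  expect_identical(subs, balanced_resample_indices(cls, 5L, seed = 4L))
  # equal class sizes: every subset is the whole cohort
  cls2 <- setNames(rep(c("tumor", "normal"), each = 6), sprintf("t%02d", 1:12))
  subs2 <- balanced_resample_indices(cls2, 3L, seed = 1L)
  for (ids in subs2) expect_setequal(ids, names(cls2))
})

test_that("planted differential features are recovered and the null stays quiet", {
  co <- small_cohort()
  cfg <- fast_config()
  filt <- quantile_filter(co$expression$genes, cfg$quantile_cut)
  de <- call_degs(filt, cfg)
  truth <- co$truth
  expect_gte(length(intersect(de$up, truth$de_up)) / length(truth$de_up), 0.95)
  expect_gte(length(intersect(de$down, truth$de_down)) / length(truth$de_down),
             0.95)
  nulls <- setdiff(rownames(filt$counts), c(truth$de_up, truth$de_down))
  false_calls <- intersect(c(de$up, de$down), nulls)
  expect_lte(length(false_calls) / length(nulls), 0.01)
  expect_length(intersect(de$up, de$down), 0L)
  # status column is consistent with the sets
  expect_setequal(de$table$feature_id[de$table$status == "up"], de$up)
})

test_that("combining calls across resamples by intersection is monotone", {
  d <- small_design(n_tumor = 18L, n_normal = 9L, lfc_effect = 1.2,
                    nb_dispersion = 0.3)
  co <- generate_cohort(d)
  filt <- quantile_filter(co$expression$genes, 0.25)
  de1 <- call_degs(filt, fast_config(n_resamples = 1L))
  de4 <- call_degs(filt, fast_config(n_resamples = 4L))
  expect_true(all(de4$up %in% de1$up))
  expect_true(all(de4$down %in% de1$down))
})
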