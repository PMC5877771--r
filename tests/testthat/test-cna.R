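seg_df <- function(markers, means, sample = "S1", chrom = "chr1") {
  n <- length(markers)
  starts <- seq(0L, by = 1000L, length.out = n)
  seg_profiles(data.frame(sample = sample, chrom = chrom,
                          start = starts, end = starts + 1000L,
                          n_markers = as.integer(markers), seg_mean = means))
}

test_that("small segments are absorbed into the closest neighbor by copy number", {
  seg <- seg_df(c(10, 2, 10), c(0.0, 0.4, 0.5))
  out <- merge_small_segments(seg, 4L)
  expect_equal(nrow(out), 2L)
  right <- out[out$start == 1000L, ]
  expect_equal(right$n_markers, 12L)
  expect_equal(right$seg_mean, (2 * 0.4 + 10 * 0.5) / 12)
  expect_equal(right$end, 3000L)
  # nothing below threshold: identity
  seg2 <- seg_df(c(10, 8, 12), c(0, 0.2, 0.4))
  expect_equal(merge_small_segments(seg2, 4L), seg2)
  # equidistant neighbors: absorbed left
  seg3 <- seg_df(c(10, 2, 10), c(0.1, 0.3, 0.5))
  out3 <- merge_small_segments(seg3, 4L)
  left <- out3[out3$start == 0L, ]
  expect_equal(left$n_markers, 12L)
  expect_equal(left$end, 2000L)
})

test_that("segment merging conserves the marker total per chromosome", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    seg <- seg_df(sample(1:12, n, TRUE), round(rnorm(n, 0, 0.3), 3))
    out <- merge_small_segments(seg, 4L)
    expect_equal(sum(out$n_markers), sum(seg$n_markers))
    expect_true(all(out$n_markers >= 4) || nrow(out) == 1)
  }
})

test_that("gene scores combine frequency and amplitude", {
  ann <- genome_annotation(data.frame(
    feature_id = "G1", chrom = "chr1", start = 100L, end = 900L,
    feature_kind = "gene"))
  mk <- function(means) {
    seg_profiles(do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(sample = sprintf("S%02d", i), chrom = "chr1", start = 0L,
                 end = 1000L, n_markers = 10L, seg_mean = means[i])
    })))
  }
  # every sample at +0.8
  sc <- gene_level_scores(mk(rep(0.8, 10)), ann)
  expect_equal(sc$g_amp, 0.8)
  expect_equal(sc$g_del, 0)
  # 8 of 10 samples at +0.8
  sc2 <- gene_level_scores(mk(c(rep(0.8, 8), 0, 0)), ann)
  expect_equal(sc2$g_amp, 0.64)
  # sub-threshold amplitudes score zero
  sc3 <- gene_level_scores(mk(runif(10, -0.09, 0.09)), ann)
  expect_equal(sc3$g_amp, 0)
  expect_equal(sc3$g_del, 0)
})

test_that("gene scores are invariant to mean-preserving segment splits", {
  ann <- genome_annotation(data.frame(
    feature_id = c("G1", "G2"), chrom = "chr1",
    start = c(100L, 1500L), end = c(900L, 1900L), feature_kind = "gene"))
  whole <- seg_profiles(data.frame(sample = "S1", chrom = "chr1", start = 0L,
                                   end = 2000L, n_markers = 20L, seg_mean = 0.5))
  split2 <- seg_profiles(data.frame(sample = "S1", chrom = "chr1",
                                    start = c(0L, 800L), end = c(800L, 2000L),
                                    n_markers = c(8L, 12L), seg_mean = 0.5))
  expect_equal(gene_level_scores(whole, ann)[, c("g_amp", "g_del")],
               gene_level_scores(split2, ann)[, c("g_amp", "g_del")])
})

test_that("permutation q-values flag a planted amplification and spare the null", {
  n_genes <- 501L
  ann <- genome_annotation(data.frame(
    feature_id = sprintf("G%03d", seq_len(n_genes)), chrom = "chr1",
    start = seq(0L, by = 2000L, length.out = n_genes),
    end = seq(0L, by = 2000L, length.out = n_genes) + 1000L,
    feature_kind = "gene"))
  chrom_end <- 2000L * n_genes
  g250 <- ann[250, ]
  mk_sample <- function(s, amplified) {
    if (amplified) {
      data.frame(sample = s, chrom = "chr1",
                 start = c(0L, g250$start, g250$end),
                 end = c(g250$start, g250$end, chrom_end),
                 n_markers = c(50L, 10L, 50L), seg_mean = c(0, 0.8, 0))
    } else {
      data.frame(sample = s, chrom = "chr1", start = 0L, end = chrom_end,
                 n_markers = 100L, seg_mean = 0)
    }
  }
  seg <- seg_profiles(do.call(rbind, lapply(1:20, function(i) {
    mk_sample(sprintf("S%02d", i), i <= 16)
  })))
  sc <- gene_level_scores(seg, ann)
  qv <- permutation_q(sc, ann, n_perm = 200L, seed = 3L)
  expect_lt(qv$q_amp[qv$gene_id == "G250"], 0.25)
  # a fully null profile yields (almost) no calls
  seg0 <- seg_profiles(do.call(rbind, lapply(1:20, function(i) {
    df <- mk_sample(sprintf("S%02d", i), FALSE)
    df$seg_mean <- rnorm(1, 0, 0.02)
    df
  })))
  sc0 <- gene_level_scores(seg0, ann)
  qv0 <- permutation_q(sc0, ann, n_perm = 50L, seed = 3L)
  calls0 <- call_cna_genes(sc0, qv0)
  expect_lte((length(calls0$amplified) + length(calls0$deleted)) / n_genes,
             0.02)
  # identical amplitudes everywhere: every permutation reproduces the data
  seg1 <- seg_profiles(do.call(rbind, lapply(1:6, function(i) {
    data.frame(sample = sprintf("S%02d", i), chrom = "chr1", start = 0L,
               end = chrom_end, n_markers = 100L, seg_mean = 0.5)
  })))
  sc1 <- gene_level_scores(seg1, ann)
  qv1 <- permutation_q(sc1, ann, n_perm = 20L, seed = 1L)
  expect_true(all(qv1$p_amp == 1))
  expect_error(permutation_q(sc1, ann, n_perm = 10L), "n_perm")
})

test_that("CNA gene calls are exclusive and empty on empty input", {
  ann <- genome_annotation(data.frame(
    feature_id = c("G1", "G2"), chrom = "chr1",
    start = c(0L, 5000L), end = c(1000L, 6000L), feature_kind = "gene"))
  empty <- seg_profiles(data.frame(sample = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   n_markers = integer(), seg_mean = numeric()))
  sc <- gene_level_scores(empty, ann)
  expect_true(all(sc$g_amp == 0 & sc$g_del == 0))
  co <- small_cohort()
  sc2 <- gene_level_scores(co$segments, co$annotation)
  qv2 <- permutation_q(sc2, co$annotation, n_perm = 50L, seed = 2L)
  calls <- call_cna_genes(sc2, qv2)
  expect_length(intersect(calls$amplified, calls$deleted), 0L)
})

test_that("miRNA loci inherit direction-concordant copy-number calls", {
  ann <- genome_annotation(data.frame(
    feature_id = c("G1", "G2", "miR.a", "miR.b", "miR.c"),
    chrom = "chr1",
    start = c(0L, 10000L, 100L, 10100L, 20000L),
    end = c(1000L, 11000L, 300L, 10300L, 20200L),
    feature_kind = c("gene", "gene", "mirna", "mirna", "mirna")))
  calls <- list(amplified = "G2", deleted = "G1")
  dirs <- c(miR.a = "down", miR.b = "down", miR.c = "down")
  res <- mirna_cna_overlap(dirs, calls, ann)
  # miR.a: down inside deleted G1 -> concordant; miR.b: down inside
  # amplified G2 -> discordant; miR.c: no overlap
  expect_equal(res$mirna_id, "miR.a")
  expect_equal(res$cna, "deleted")
  dirs2 <- c(miR.b = "up")
  res2 <- mirna_cna_overlap(dirs2, calls, ann)
  expect_equal(res2$mirna_id, "miR.b")
  expect_equal(res2$cna, "amplified")
  expect_warning(none <- mirna_cna_overlap(c(x = "up"), calls,
                                           ann[ann$feature_kind == "gene", ]),
                 "no miRNA loci")
  expect_equal(nrow(none), 0L)
})
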