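test_that("cohort generation is deterministic under a fixed seed", {
  d <- small_design(seed = 13L)
  a <- generate_cohort(d)
  b <- generate_cohort(d)
  expect_identical(a$expression$genes$counts, b$expression$genes$counts)
  expect_identical(a$expression$mirnas$counts, b$expression$mirnas$counts)
  expect_identical(a$segments, b$segments)
  expect_identical(a$targets, b$targets)
  expect_identical(a$truth$master_mirna, b$truth$master_mirna)
})

test_that("a zero effect size leaves planted features at null fold change", {
  d <- small_design(lfc_effect = 0, n_tumor = 30L, n_normal = 30L,
                    n_core_up = 40L, n_core_down = 40L, n_genes = 400L)
  tr <- ground_truth(d)
  expr <- generate_expression(d, tr)
  cm <- expr$genes
  tum <- cm$sample_class == "tumor"
  planted <- c(tr$de_up, tr$de_down)
  lfc <- log2((rowMeans(cm$counts[planted, tum]) + 0.5) /
              (rowMeans(cm$counts[planted, !tum]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("generated null counts carry the designed NB dispersion", {
  d <- small_design(lfc_effect = 0, n_genes = 2000L, n_mirnas = 10L,
                    n_tumor = 15L, n_normal = 15L, nb_dispersion = 0.2,
                    n_core_up = 1L, n_core_down = 1L, n_decoys_per_layer = 0L,
                    n_network_genes = 4L, n_overlap_genes = 2L,
                    n_up_mirnas = 2L, n_down_mirnas = 2L,
                    master_mirna_n_targets = 2L)
  cm <- generate_expression(d)$genes
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, var)
  phi_mm <- mean((v - m) / m^2)   # method-of-moments, averaged over features
  expect_lt(abs(phi_mm - 0.2) / 0.2, 0.25)
})

test_that("planted segments carry the designed amplitude at the designed frequency", {
  d <- small_design(n_tumor = 40L)
  tr <- ground_truth(d)
  ann <- generate_annotation(d, tr)
  seg <- generate_segments(d, tr, ann)
  sc <- gene_level_scores(seg, ann)
  planted_amp <- sc$g_amp[sc$gene_id %in% tr$planted_amplified]
  # expectation: amplitude x sample fraction = 0.8 * 0.8 = 0.64
  expect_lt(abs(mean(planted_amp) - 0.64), 0.05)
  planted_del <- sc$g_del[sc$gene_id %in% tr$planted_deleted]
  expect_lt(abs(mean(planted_del) - 0.64), 0.05)
  expect_true(all(seg$n_markers >= 4))
  # zero amplitude: nothing exceeds the calling thresholds
  d0 <- small_design(cna_amplitude = 0)
  tr0 <- ground_truth(d0)
  sc0 <- gene_level_scores(generate_segments(d0, tr0), generate_annotation(d0, tr0))
  expect_true(all(sc0$g_amp == 0))
  expect_true(all(sc0$g_del == 0))
})

test_that("target votes separate true pairs from noise at the consensus threshold", {
  d <- small_design()          # signal 7 votes, noise 2
  tr <- ground_truth(d)
  db <- generate_target_db(d, tr)
  cons <- consensus(db, 5L)
  got <- paste(cons$pairs$mirna, cons$pairs$gene)
  want <- paste(tr$true_pairs$mirna, tr$true_pairs$gene)
  expect_setequal(got, want)
  # sub-threshold signal yields an empty consensus
  d4 <- small_design(target_vote_signal = 4L)
  db4 <- generate_target_db(d4, ground_truth(d4))
  expect_equal(nrow(consensus(db4, 5L)$pairs), 0L)
})

test_that("ground truth is direction-consistent by construction", {
  tr <- ground_truth(small_design())
  expect_true(all(tr$core_up %in% tr$planted_amplified))
  expect_true(all(tr$core_down %in% tr$planted_deleted))
  dirs <- tr$deregulated_mirnas
  for (g in tr$core_up) {
    regs <- tr$true_pairs$mirna[tr$true_pairs$gene == g]
    expect_gte(length(regs), 1L)
    expect_true(all(dirs[regs] == "down"))
  }
  for (g in tr$core_down) {
    regs <- tr$true_pairs$mirna[tr$true_pairs$gene == g]
    expect_gte(length(regs), 1L)
    expect_true(all(dirs[regs] == "up"))
  }
  expect_true(all(tr$master_targets %in% tr$network_genes))
  expect_equal(unname(dirs[tr$master_mirna]), "up")
})

test_that("a written cohort round-trips through the readers", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$expression$genes$counts, co$expression$genes$counts)
  expect_equal(back$segments, co$segments)
  expect_setequal(paste(back$targets$mirna, back$targets$gene, back$targets$database),
                  paste(co$targets$mirna, co$targets$gene, co$targets$database))
  expect_setequal(network_gene_set(back$network), co$truth$network_genes)
  expect_setequal(back$truth$core_up, co$truth$core_up)
  expect_setequal(back$truth$core_down, co$truth$core_down)
  expect_identical(back$truth$master_mirna, co$truth$master_mirna)
})
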