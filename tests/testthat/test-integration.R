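cons_of <- function(pairs) {
  triples <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(mirna = pairs$mirna[i], gene = pairs$gene[i],
               database = TARGET_DATABASES[1:5], stringsAsFactors = FALSE)
  }))
  consensus(triples, 5L)
}

test_that("expression-CNA intersection keeps only direction-concordant genes", {
  ec <- intersect_expression_cna(up = c("A", "B", "C"), down = c("D", "E"),
                                 amplified = c("B", "C", "D"),
                                 deleted = c("E", "F"))
  expect_equal(ec$up_amplified, c("B", "C"))
  expect_equal(ec$down_deleted, "E")
  # disjoint inputs
  ec0 <- intersect_expression_cna("A", "B", "C", "D")
  expect_length(ec0$up_amplified, 0L)
  expect_length(ec0$down_deleted, 0L)
  # brute-force membership oracle on random sets
  set.seed(2)
  pool <- paste0("g", 1:40)
  up <- sample(pool, 15); down <- sample(setdiff(pool, up), 10)
  amp <- sample(pool, 12); del <- sample(setdiff(pool, amp), 12)
  ec2 <- intersect_expression_cna(up, down, amp, del)
  expect_setequal(ec2$up_amplified, pool[pool %in% up & pool %in% amp])
  expect_setequal(ec2$down_deleted, pool[pool %in% down & pool %in% del])
})

test_that("CNA-target and expression-target intersections cross directions", {
  cons <- cons_of(data.frame(mirna = c("mU", "mD", "mD"),
                             gene = c("gDel", "gAmp", "gOther")))
  ct <- intersect_cna_targets(amplified = c("gAmp", "gX"),
                              deleted = c("gDel", "gY"),
                              cons, up_mirnas = "mU", down_mirnas = "mD")
  expect_equal(ct$amplified_target_of_down, "gAmp")
  expect_equal(ct$deleted_target_of_up, "gDel")
  # an amplified gene targeted only by an up-miRNA is excluded
  cons2 <- cons_of(data.frame(mirna = "mU", gene = "gAmp"))
  ct2 <- intersect_cna_targets("gAmp", character(), cons2, "mU", "mD")
  expect_length(ct2$amplified_target_of_down, 0L)
  et <- intersect_expression_targets(up = "gAmp", down = "gDel", cons,
                                     up_mirnas = "mU", down_mirnas = "mD")
  expect_equal(et$up_target_of_down, "gAmp")
  expect_equal(et$down_target_of_up, "gDel")
  # empty miRNA sets give empty results
  et0 <- intersect_expression_targets("gAmp", "gDel", cons,
                                      character(), character())
  expect_length(et0$up_target_of_down, 0L)
})

test_that("core genes satisfy the triple direction rule", {
  cons <- cons_of(data.frame(
    mirna = c("mD1", "mU1", "mU2", "mU1", "mD2"),
    gene = c("coreUp", "coreDown", "coreDown", "noCna", "wrongDir")))
  core <- core_genes(up_amplified = c("coreUp", "lonely"),
                     down_deleted = c("coreDown", "wrongDir"),
                     cons, up_mirnas = c("mU1", "mU2"),
                     down_mirnas = c("mD1", "mD2"))
  expect_setequal(core$gene_id, c("coreUp", "coreDown"))
  expect_equal(core$regulating_mirnas[core$gene_id == "coreUp"], "mD1")
  expect_equal(core$regulating_mirnas[core$gene_id == "coreDown"], "mU1,mU2")
  # wrongDir is down/deleted but only targeted by a down-miRNA
  expect_false("wrongDir" %in% core$gene_id)
  # containment in the parents
  expect_true(all(core$gene_id[core$direction == "up"] %in% c("coreUp", "lonely")))
  # a miRNA in both direction sets aborts
  expect_error(core_genes("a", "b", cons, up_mirnas = "mX", down_mirnas = "mX"),
               "both direction sets")
})

test_that("core genes equal a brute-force triple filter on random layers", {
  set.seed(33)
  pool <- paste0("g", 1:60)
  mirs <- paste0("m", 1:10)
  up_m <- mirs[1:5]; down_m <- mirs[6:10]
  pairs <- unique(data.frame(mirna = sample(mirs, 80, TRUE),
                             gene = sample(pool, 80, TRUE)))
  cons <- cons_of(pairs)
  up_amp <- sample(pool, 20)
  down_del <- sample(setdiff(pool, up_amp), 20)
  core <- core_genes(up_amp, down_del, cons, up_m, down_m)
  oracle_up <- Filter(function(g) {
    any(pairs$mirna[pairs$gene == g] %in% down_m)
  }, up_amp)
  oracle_down <- Filter(function(g) {
    any(pairs$mirna[pairs$gene == g] %in% up_m)
  }, down_del)
  expect_setequal(core$gene_id[core$direction == "up"], oracle_up)
  expect_setequal(core$gene_id[core$direction == "down"], oracle_down)
})

test_that("venn accounting matches brute-force region classification", {
  s <- paste0("x", 1:5)
  expect_equal(unname(venn_summary(s, s, s)),
               c(0L, 0L, 0L, 0L, 0L, 0L, 5L))
  v <- venn_summary(c("a", "b"), c("c"), c("d", "e", "f"))
  expect_equal(unname(v), c(2L, 1L, 3L, 0L, 0L, 0L, 0L))
  set.seed(41)
  pool <- paste0("g", 1:30)
  A <- sample(pool, 12); B <- sample(pool, 10); C <- sample(pool, 15)
  v2 <- venn_summary(A, B, C)
  regions <- table(factor(paste0(
    ifelse(pool %in% A, "A", ""), ifelse(pool %in% B, "B", ""),
    ifelse(pool %in% C, "C", "")),
    levels = c("A", "B", "C", "AB", "AC", "BC", "ABC")))
  expect_equal(unname(v2), unname(as.integer(regions)))
  expect_equal(sum(v2), length(unique(c(A, B, C))))
})

test_that("signature overlap matches case-insensitively with provenance", {
  dir <- withr::local_tempdir()
  writeLines(c("trib1", "OTHER1"), file.path(dir, "sigA.txt"))
  writeLines(c("CLU", "TRIB1"), file.path(dir, "sigB.txt"))
  ov <- signature_overlap(c("TRIB1", "CLU", "KLF5"),
                          c(file.path(dir, "sigA.txt"),
                            file.path(dir, "sigB.txt")))
  expect_equal(ov$gene_id, c("CLU", "TRIB1"))
  expect_equal(ov$signatures[ov$gene_id == "TRIB1"], "sigA,sigB")
  expect_true(all(ov$gene_id %in% c("TRIB1", "CLU", "KLF5")))
  expect_equal(nrow(signature_overlap(c("A", "B"), character())), 0L)
})
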