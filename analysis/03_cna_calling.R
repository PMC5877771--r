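#!/usr/bin/env Rscript
# Gene-level copy-number calling: join under-supported segments, score
# amplification/deletion per gene (frequency x amplitude), and attach
# permutation q-values.
source("analysis/00_common.R")

co <- cohort_or_stop()
seg <- merge_small_segments(co$segments, CONFIG$min_markers)
scores <- gene_level_scores(seg, co$annotation,
                            CONFIG$cna_gain_threshold,
                            CONFIG$cna_loss_threshold)
qv <- permutation_q(scores, co$annotation, CONFIG$n_perm, SEED,
                    CONFIG$cna_gain_threshold, CONFIG$cna_loss_threshold)
calls <- call_cna_genes(scores, qv, CONFIG)

message(length(calls$amplified), " amplified / ",
        length(calls$deleted), " deleted genes at q < ",
        CONFIG$cna_q_threshold)
save_tsv(calls$table, "results/cna_genes.tsv")
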