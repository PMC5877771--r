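#!/usr/bin/env Rscript
# Cross-validated random-forest AUC of the candidate feature sets
# (approaches I-VI) plus the matched-size random-gene baseline.
source("analysis/00_common.R")

co <- cohort_or_stop()
report <- run_all(co, CONFIG, classify = TRUE)
aucs <- report_summary(report)$auc_mean
for (a in names(aucs)) message("approach ", a, ": mean AUC ",
                               round(aucs[[a]], 3))

labels <- co$expression$genes$sample_class
core_true <- c(co$truth$core_up, co$truth$core_down)
planted <- cv_auc(build_feature_matrix(core_true, co$expression$genes),
                  labels, CONFIG, "planted")
baseline <- random_gene_baseline(length(core_true), 11L,
                                 co$expression$genes, labels, CONFIG,
                                 seed = SEED)
base_auc <- vapply(baseline, `[[`, 0, "auc_mean")
message("planted-signature AUC ", round(planted$auc_mean, 3),
        " vs random-baseline median ", round(median(base_auc), 3))

out <- data.frame(approach = c(names(aucs), "planted",
                               paste0("random_", seq_along(base_auc))),
                  auc_mean = c(unlist(aucs), planted$auc_mean, base_auc))
save_tsv(out, "results/classification_auc.tsv")
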