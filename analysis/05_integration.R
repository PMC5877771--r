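#!/usr/bin/env Rscript
# Full integration pass: run every stage in order, nominate core genes,
# intersect with the packaged signature files and write the run report.
source("analysis/00_common.R")

co <- cohort_or_stop()
report <- run_all(co, CONFIG, classify = FALSE, out_dir = "results/run")

cnt <- report$counts
message("DE genes: ", cnt$de_up, " up / ", cnt$de_down, " down")
message("expression-CNA intersection: ", cnt$up_amplified, " up+amplified, ",
        cnt$down_deleted, " down+deleted")
message("core genes: ", cnt$core_genes,
        " (signature overlap: ", cnt$overlap_genes, ")")
if (!is.null(report$truth_scores)) {
  message("core precision ", report$truth_scores$core$precision,
          ", recall ", report$truth_scores$core$recall)
}
save_tsv(report$core, "results/core_genes.tsv")
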