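#!/usr/bin/env Rscript
# Fisher-exact enrichment of every deregulated miRNA's consensus targets
# among the co-expression network genes; rank master-regulator candidates.
source("analysis/00_common.R")

co <- cohort_or_stop()
report <- run_all(co, CONFIG, classify = FALSE)
message(report$counts$enriched_mirnas, " enriched miRNA(s); top: ",
        report$top_mirna)
if (!is.null(co$truth)) {
  message("planted master ", co$truth$master_mirna, " rank: ",
          report$truth_scores$master_mirna_rank)
}
save_tsv(report$enrichment, "results/network_enrichment.tsv")
save_tsv(report$masters, "results/master_mirna_ranking.tsv")
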