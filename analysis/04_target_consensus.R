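#!/usr/bin/env Rscript
# Reduce the multi-database target table to consensus miRNA->gene sets
# (a pair must be predicted by at least 5 of the 10 databases).
source("analysis/00_common.R")

co <- cohort_or_stop()
cons <- consensus(co$targets, CONFIG$consensus_min_votes)
message(nrow(cons$pairs), " consensus pairs over ",
        length(cons$forward), " miRNAs and ", length(cons$reverse), " genes")
save_tsv(cons$pairs, "results/consensus_targets.tsv")
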