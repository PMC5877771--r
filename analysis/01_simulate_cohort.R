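#!/usr/bin/env Rscript
# Generate the synthetic multi-omic cohort used by every later step:
# 40 tumor vs 40 normal samples, 3000 genes / 150 miRNAs, 20 planted core
# genes (10 up+amplified, 10 down+deleted), 40 single/double-layer decoys,
# 24 deregulated miRNAs including one planted master regulator of the
# 19-gene co-expression network.
source("analysis/00_common.R")

design <- simulation_design(rng_seed = SEED)
res <- write_cohort(design, COHORT_DIR)
tr <- res$cohort$truth

message("cohort written to ", COHORT_DIR)
message("planted core genes: ", length(tr$core_up), " up / ",
        length(tr$core_down), " down")
message("planted master miRNA: ", tr$master_mirna, " targeting ",
        length(tr$master_targets), " network genes")
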