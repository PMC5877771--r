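#!/usr/bin/env Rscript
# Re-derive the worked example from the packaged result-table fixtures:
# the expression-CNA gene accounting, the core-gene accounting, the
# four-gene signature overlap, the network size and the cohort totals.
source("analysis/00_common.R")

v <- validate_tables()
message("expression-CNA genes: ", v$table1$n_genes, " (",
        v$table1$up_amplified, " up+amplified, ",
        v$table1$down_deleted, " down+deleted)")
message("core genes: ", v$table2$n_core, " (", v$table2$up_amplified,
        " up, ", v$table2$down_deleted, " down)")
message("signature overlap: ", paste(v$signature_overlap$genes, collapse = ", "))
message("network: ", v$table4$n_genes, " genes / ", v$table4$n_edges, " edges")
message("master miRNA ", v$network_mirna$id, " targets ",
        v$network_mirna$n_network_targets, " network genes")
message("cohort: ", v$table5$pc_by_age, " PC / ", v$table5$controls_by_age,
        " controls")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(v, "results/table_accounting.json",
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote results/table_accounting.json")
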