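#!/usr/bin/env Rscript
# Quantile-filter the count matrices and call differentially expressed
# genes and miRNAs with the exact NB test under balanced resampling.
source("analysis/00_common.R")

co <- cohort_or_stop()
genes_f <- quantile_filter(co$expression$genes, CONFIG$quantile_cut)
mirnas_f <- quantile_filter(co$expression$mirnas, CONFIG$quantile_cut)
de_genes <- call_degs(genes_f, CONFIG)
de_mirnas <- call_degs(mirnas_f, CONFIG)

message(nrow(genes_f$counts), " genes pass the filter; ",
        length(de_genes$up), " up / ", length(de_genes$down), " down")
message(nrow(mirnas_f$counts), " miRNAs pass the filter; ",
        length(de_mirnas$up), " up / ", length(de_mirnas$down), " down")
message("common dispersion (first resample): ",
        signif(de_genes$dispersion$phi, 3))

save_tsv(de_genes$table, "results/de_genes.tsv")
save_tsv(de_mirnas$table, "results/de_mirnas.tsv")
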