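Machine-readable transcriptions of the printed result tables of the source
study, used by validate_tables() and the acceptance script.

table1_expression_cna.tsv   genes from the expression x copy-number
                            intersection (alteration, gene, cytoband)
table2_core_genes.tsv       core genes with their regulating miRNAs
table3_signature_*.txt      published prostate-cancer gene signatures; the
                            study prints each signature's size and the one
                            gene shared with the core set, so every file
                            carries that printed gene padded to the printed
                            size with clearly synthetic SYNTH_FILLER_*
                            placeholder symbols
table4_coexpression_edges.tsv  the co-expression network edge list
table5_cohort.tsv           cohort characteristics by age and Gleason score
network_mirna_targets.tsv   the network sub-pathway regulated by the
                            nominated master miRNA
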