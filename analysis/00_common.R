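# shared settings for the analysis drivers: one seed, one config, and the
# cohort directory every later step reads from
suppressPackageStartupMessages(library(coremir))

SEED <- 1L
COHORT_DIR <- "results/cohort"
CONFIG <- analysis_config(rng_seed = SEED)

cohort_or_stop <- function() {
  if (!dir.exists(COHORT_DIR)) {
    stop("run analysis/01_simulate_cohort.R first (", COHORT_DIR, " missing)")
  }
  read_cohort(COHORT_DIR)
}

save_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
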