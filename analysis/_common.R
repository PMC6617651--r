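# Shared study definition for the analysis scripts. Every script sources
# this file; the dataset is regenerated deterministically from the seed,
# so scripts can be run independently or in order.

library(methsig)

STUDY_SEED <- 20260901L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

study_params <- sim_params(seed = STUDY_SEED)  # 20k probes, 8 vs 23, 300 CpGs
study_config <- default_config(n_boot = 1000L, seed = STUDY_SEED)

study <- generate_dataset(study_params)
panel <- generate_reference_panel(study_params)$panel

mono_of <- function(props, sheet)
  props$Mono[match(sheet$sample_id, props$sample_id)]

save_tsv <- function(df, name) {
  data.table::fwrite(df, file.path(RESULTS, name), sep = "\t", quote = FALSE)
  message("wrote ", file.path(RESULTS, name))
}
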