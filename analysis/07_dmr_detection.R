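#!/usr/bin/env Rscript
# Bumphunter-style DMR detection: probe clusters at gaps < 500 bp,
# candidates at |group coefficient| > 0.10, bootstrap null with 1,000
# iterations, retained at p < 0.01 with >= 4 CpGs.

source("analysis/_common.R")

bm <- read_beta_matrix(file.path(DATA_DIR, "beta_filtered.tsv"))
props <- data.table::fread(file.path(RESULTS, "proportions.tsv"),
                           data.table = FALSE)

out <- find_dmrs(bm, study$manifest, study$samples,
                 mono_of(props, study$samples), study_config)
save_tsv(out$dmrs[, setdiff(names(out$dmrs), "probes")], "dmrs.tsv")
write_dmr_bed(out$dmrs, file.path(RESULTS, "dmrs.bed"))

message(sprintf("%d candidate regions, %d reported DMRs (p < %g, >= %d CpGs), %d null areas",
                nrow(out$candidates), nrow(out$dmrs), study_config$dmr_p,
                study_config$dmr_min_len, length(out$null_areas)))
print(out$dmrs[, c("chrom", "start", "end", "n_probes", "value", "area", "p")],
      digits = 3)
message("planted DMRs:")
print(study$truth$planted_dmrs)
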