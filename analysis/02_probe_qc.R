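#!/usr/bin/env Rscript
# Apply the probe-removal rules and report per-filter counts, reading
# the study back from the files 01_simulate.R wrote (round-trip check).

source("analysis/_common.R")

bm <- read_beta_matrix(file.path(DATA_DIR, "beta.tsv"),
                       file.path(DATA_DIR, "detection_p.tsv"))
manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))

qc <- apply_probe_filters(bm, manifest, study_config)
print(qc$report)
save_tsv(qc$report$filters, "qc_report.tsv")
write_beta_matrix(qc$beta, file.path(DATA_DIR, "beta_filtered.tsv"))

# every removed probe should be a planted artifact (or extreme-beta)
removed <- setdiff(rownames(bm$beta), rownames(qc$beta$beta))
lab <- study$truth$artifact_labels
message(sprintf("%d probes removed; %.1f%% carry a planted artifact label",
                length(removed),
                100 * mean(lab$artifact[match(removed, lab$probe_id)] != "none")))
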