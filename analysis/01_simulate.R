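#!/usr/bin/env Rscript
# Generate the synthetic case-control methylation study and persist it.
#
# The cohort mirrors the signature-derivation design: 8 cases vs 23
# controls on a 20,000-probe array slice, 300 signature CpGs planted at
# |delta beta| = 0.15, blood cell-type mixing with a monocyte/CD4+ T
# composition shift in cases, and probe artifacts of every QC class.

source("analysis/_common.R")

write_beta_matrix(study$beta, file.path(DATA_DIR, "beta.tsv"),
                  file.path(DATA_DIR, "detection_p.tsv"))
write_manifest(study$manifest, file.path(DATA_DIR, "manifest.tsv"))
write_sample_sheet(study$samples, file.path(DATA_DIR, "samples.tsv"))
save_tsv(study$truth$signature, "data/truth_signature.tsv")
save_tsv(study$truth$planted_dmrs, "data/truth_dmrs.tsv")
save_tsv(study$truth$artifact_labels, "data/truth_artifacts.tsv")
save_tsv(data.frame(sample_id = rownames(study$truth$true_proportions),
                    study$truth$true_proportions),
         "data/truth_proportions.tsv")

message(sprintf("dataset: %d probes x %d samples (%d cases, %d controls)",
                nrow(study$beta$beta), ncol(study$beta$beta),
                sum(study$samples$group == "case"),
                sum(study$samples$group == "control")))
message(sprintf("planted signature: %d CpGs at |delta beta| = %.2f; %d DMRs",
                nrow(study$truth$signature), study_params$effect_delta,
                study_params$n_dmrs))
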