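#!/usr/bin/env Rscript
# Build the median reference profiles, score every sample with the
# correlation-difference episignature score, evaluate the classifier on
# held-out synthetic cases/controls, and cluster samples at the
# signature CpGs.

source("analysis/_common.R")

sig <- readLines(file.path(RESULTS, "signature_probes.txt"))
ca <- study$samples$sample_id[study$samples$group == "case"]
co <- study$samples$sample_id[study$samples$group == "control"]

model <- build_reference_profiles(study$beta$beta, sig, ca, co)
write_signature_model(model, file.path(RESULTS, "signature_model.json"))

scores <- score_samples(subset_beta(study$beta, probes = sig), model)
save_tsv(scores, "scores.tsv")
message(sprintf("derivation scores: cases %.2f..%.2f, controls %.2f..%.2f",
                min(scores$score[scores$sample_id %in% ca]),
                max(scores$score[scores$sample_id %in% ca]),
                min(scores$score[scores$sample_id %in% co]),
                max(scores$score[scores$sample_id %in% co])))

# held-out validation cohort: 10 cases, 50 controls drawn from the same
# generative model
held <- c(lapply(1:10, function(i) generate_mosaic_sample(study, 1, 7000 + i)),
          lapply(1:50, function(i) generate_mosaic_sample(study, 0, 8000 + i)))
held_scores <- data.frame(
  sample_id = vapply(held, `[[`, character(1), "sample_id"),
  truth = c(rep("pathogenic", 10), rep("benign", 50)),
  score = vapply(held, function(h)
    score_sample(h$beta[model$probes], model)$score, numeric(1)))
held_scores$label <- ifelse(held_scores$score > 0, "pathogenic", "benign")
save_tsv(held_scores, "validation_scores.tsv")
ev <- evaluate_classifier(held_scores$label, held_scores$truth)
message(sprintf("held-out validation: sensitivity %.0f%%, specificity %.0f%%",
                100 * ev$sensitivity, 100 * ev$specificity))

cl <- cluster_samples(study$beta$beta, sig)
agree <- table(cl$clusters, study$samples$group)
message("2-cut Euclidean clustering vs groups:")
print(agree)
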