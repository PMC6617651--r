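#!/usr/bin/env Rscript
# Reference-based blood cell-type deconvolution and case/control
# comparison of the estimated proportions. The monocyte estimate feeds
# the regression model downstream (monocytes and CD4+ T cells shift in
# opposite directions in cases and are correlated, so only the more
# significant of the two is used as a covariate).

source("analysis/_common.R")

props <- estimate_proportions_all(study$beta, panel)
save_tsv(props, "proportions.tsv")

tests <- compare_cell_proportions(props, study$samples$group)
save_tsv(tests, "celltype_tests.tsv")
print(tests, digits = 3)

truth <- study$truth$true_proportions
mae <- mean(abs(as.matrix(props[, colnames(truth)]) - truth))
message(sprintf("mean absolute error vs true proportions: %.4f", mae))
message(sprintf("monocyte shift: %.3f (case) vs %.3f (control), p = %.2g",
                tests$mean_case[tests$cell_type == "Mono"],
                tests$mean_control[tests$cell_type == "Mono"],
                tests$p[tests$cell_type == "Mono"]))
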