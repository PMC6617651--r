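#!/usr/bin/env Rscript
# Gene-set enrichment of the signature CpGs: foreground/background
# hypergeometric test over manifest-mapped genes (background = probes
# surviving QC), plus the 2x2 chi-square overlap test against a curated
# gene list (the design used for the autism-gene comparison).

source("analysis/_common.R")

sig <- readLines(file.path(RESULTS, "signature_probes.txt"))
bm <- read_beta_matrix(file.path(DATA_DIR, "beta_filtered.tsv"))
background <- rownames(bm$beta)

# synthetic gene sets: one enriched set seeded with signature genes,
# plus random sets of matched sizes
set.seed(STUDY_SEED)
sig_genes <- probes_to_genes(sig, study$manifest)
bg_genes <- probes_to_genes(background, study$manifest)
gene_sets <- c(
  list(signature_seeded = unique(c(sample(sig_genes, min(30, length(sig_genes))),
                                   sample(bg_genes, 40)))),
  setNames(lapply(1:5, function(i) sample(bg_genes, 70)),
           paste0("random_", 1:5)))

enr <- hypergeom_enrich(sig, background, study$manifest, gene_sets)
save_tsv(enr, "enrichment.tsv")
print(enr, digits = 3)

# 2x2 overlap of the signature gene list with a curated list that
# half-overlaps the seeded set
curated <- unique(c(sample(sig_genes, min(15, length(sig_genes))),
                    sample(setdiff(bg_genes, sig_genes), 100)))
a <- length(intersect(sig_genes, curated))
b <- length(setdiff(sig_genes, curated))
cc <- length(setdiff(curated, sig_genes))
dd <- length(setdiff(bg_genes, union(sig_genes, curated)))
x2 <- chisq_2x2(a, b, cc, dd)
message(sprintf("curated-list overlap: %d/%d signature genes; chi2 = %.1f, p = %.2g",
                a, length(sig_genes), x2$chi2, x2$p))
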