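test_that("probe clustering joins gaps < 500 and splits at exactly 500", {
  man <- tiny_manifest(c("p1", "p2", "p3"), pos = c(100L, 400L, 950L))
  cl <- cluster_probes(man, 500)
  expect_equal(unname(cl), c(1L, 1L, 2L))  # 300 < 500 joins, 550 >= 500 splits
  man2 <- tiny_manifest(c("a", "b"), pos = c(1000L, 1500L))
  expect_equal(length(unique(cluster_probes(man2, 500))), 2)  # gap == 500
  man3 <- tiny_manifest("solo", pos = 42L)
  expect_equal(unname(cluster_probes(man3, 500)), 1L)
  # chromosomes never share a cluster
  man4 <- tiny_manifest(c("x", "y"), chrom = c("chr1", "chr2"),
                        pos = c(100L, 150L))
  expect_equal(length(unique(cluster_probes(man4, 500))), 2)
  man5 <- tiny_manifest(c("d1", "d2"), pos = c(7L, 7L))
  expect_error(cluster_probes(man5, 500), "duplicate")
})

test_that("candidate runs require same sign above the cutoff", {
  man <- tiny_manifest(c("p1", "p2", "p3"), pos = c(100L, 200L, 300L))
  cl <- cluster_probes(man, 500)
  coefs <- c(p1 = 0.15, p2 = 0.12, p3 = -0.2)
  cand <- find_candidate_regions(coefs, cl, man, cutoff = 0.10)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$n_probes, c(2L, 1L))
  expect_equal(cand$value, c(0.135, -0.2))
  expect_equal(cand$area, c(0.27, 0.2), tolerance = 1e-12)

  none <- find_candidate_regions(c(p1 = 0.1, p2 = -0.05, p3 = 0.08),
                                 cl, man, cutoff = 0.10)
  expect_equal(nrow(none), 0)  # cutoff is strict: 0.10 does not pass
})

test_that("runs never span cluster boundaries", {
  man <- tiny_manifest(paste0("p", 1:4), pos = c(100L, 200L, 5000L, 5100L))
  cl <- cluster_probes(man, 500)
  coefs <- setNames(rep(0.2, 4), paste0("p", 1:4))
  cand <- find_candidate_regions(coefs, cl, man, cutoff = 0.10)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$n_probes, c(2L, 2L))
})

test_that("flipping the group coding negates values and preserves areas", {
  man <- tiny_manifest(paste0("p", 1:5), pos = c(100L, 200L, 300L, 400L, 500L))
  cl <- cluster_probes(man, 500)
  set.seed(1)
  coefs <- setNames(runif(5, 0.12, 0.3) * sample(c(-1, 1), 5, TRUE),
                    paste0("p", 1:5))
  a <- find_candidate_regions(coefs, cl, man)
  b <- find_candidate_regions(-coefs, cl, man)
  expect_equal(sort(a$area), sort(b$area), tolerance = 1e-12)
  expect_equal(sort(a$value), sort(-b$value), tolerance = 1e-12)
})

test_that("add-one bootstrap p-values follow the pooled formula", {
  cand <- data.frame(chrom = "chr1", start = 1L, end = 500L, n_probes = 6L,
                     value = 0.15, area = 0.9, first_probe = "p1",
                     probes = "p1")
  null_areas <- runif(999, 0, 0.5)  # all below the observed area
  out <- call_dmrs(cand, null_areas, p_cut = 0.01, min_len = 4)
  expect_equal(out$p, 1 / 1000)
  # a 3-probe candidate with a tiny p is still rejected by min_len = 4
  cand3 <- cand; cand3$n_probes <- 3L
  expect_equal(nrow(call_dmrs(cand3, null_areas, 0.01, 4)), 0)
  # n_boot = 1 style bound: p >= 1 / (1 + N)
  expect_gte(call_dmrs(cand, 0.1, p_cut = 1, min_len = 1)$p, 1 / 2)
  expect_error(call_dmrs(cand, numeric(0)), "empty null")
})

test_that("the bootstrap null is deterministic under a fixed seed", {
  ds <- small_sim(seed = 41)
  man <- ds$manifest[ds$manifest$chrom == "chr1", ]
  bm <- subset_beta(ds$beta, probes = man$probe_id)
  cl <- cluster_probes(man, 500)
  pan <- generate_reference_panel(ds$params)
  props <- estimate_proportions_all(ds$beta, pan$panel)
  X <- build_design(ds$samples, mono_of(props, ds$samples))
  n1 <- bootstrap_null(bm$beta, X, cl, man, cutoff = 0.10, n_boot = 20, seed = 5)
  n2 <- bootstrap_null(bm$beta, X, cl, man, cutoff = 0.10, n_boot = 20, seed = 5)
  expect_identical(n1, n2)
})

test_that("a planted DMR is detected and nulls yield none", {
  ds <- small_sim(seed = 42)
  pan <- generate_reference_panel(ds$params)
  props <- estimate_proportions_all(ds$beta, pan$panel)
  cfg <- default_config(n_boot = 60)
  qc <- apply_probe_filters(ds$beta, ds$manifest, cfg)
  out <- find_dmrs(qc$beta, ds$manifest, ds$samples,
                   mono_of(props, ds$samples), cfg)
  planted <- ds$truth$planted_dmrs
  hits <- merge(out$dmrs, planted, by = c("chrom", "start"))
  expect_equal(nrow(hits), nrow(planted))
  expect_true(all(out$dmrs$n_probes >= 4))
  # no reported DMR spans a cluster boundary
  for (i in seq_len(nrow(out$dmrs))) {
    pr <- strsplit(out$dmrs$probes[i], ";")[[1]]
    expect_equal(length(unique(out$clusters[pr])), 1)
  }

  # null dataset: no false DMRs
  dn <- generate_dataset(sim_params(n_probes = 2500, n_signature = 60,
                                    effect_delta = 0, n_dmrs = 2, dmr_len = 6,
                                    seed = 43))
  pann <- generate_reference_panel(dn$params)
  propsn <- estimate_proportions_all(dn$beta, pann$panel)
  qcn <- apply_probe_filters(dn$beta, dn$manifest, cfg)
  outn <- find_dmrs(qcn$beta, dn$manifest, dn$samples,
                    mono_of(propsn, dn$samples), cfg)
  expect_equal(nrow(outn$dmrs), 0)
})

test_that("BED export converts closed 1-based probe spans to half-open", {
  dmrs <- data.frame(chrom = "chr3", start = 1001L, end = 1500L,
                     n_probes = 5L, value = 0.2, area = 1.0,
                     first_probe = "p1", probes = "p1", p = 0.001)
  f <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, 1000L)
  expect_equal(bed$V3, 1500L)
  expect_equal(bed$V6, "+")
})
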