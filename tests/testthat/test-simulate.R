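test_that("same seed reproduces the dataset exactly; seeds differ otherwise", {
  p <- sim_params(n_probes = 800, n_signature = 20, n_dmrs = 1, dmr_len = 4,
                  seed = 7)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$beta$beta, d2$beta$beta)
  expect_identical(d1$truth$signature, d2$truth$signature)
  d3 <- generate_dataset(sim_params(n_probes = 800, n_signature = 20,
                                    n_dmrs = 1, dmr_len = 4, seed = 8))
  expect_false(identical(d1$beta$beta, d3$beta$beta))
})

test_that("planted effects are recovered by empirical group means", {
  ds <- generate_dataset(sim_params(n_probes = 5000, n_signature = 300,
                                    seed = 1))
  sig <- ds$truth$signature
  ca <- ds$samples$sample_id[ds$samples$group == "case"]
  co <- ds$samples$sample_id[ds$samples$group == "control"]
  db <- rowMeans(ds$beta$beta[sig$probe_id, ca]) -
        rowMeans(ds$beta$beta[sig$probe_id, co])
  expect_lt(abs(mean(abs(db)) - 0.15), 0.03)
  expect_gt(mean(sign(db) == sign(sig$effect)), 0.99)
})

test_that("null data (effect 0) yields ~5% two-sample t rejections", {
  # fully null: no planted effect and no group composition shift
  ds <- generate_dataset(sim_params(n_probes = 3000, n_signature = 100,
                                    effect_delta = 0, n_dmrs = 0,
                                    var_probe_frac = 0,
                                    dirichlet_case = rep(25, 6),
                                    dirichlet_control = rep(25, 6), seed = 11))
  grp <- ds$samples$group
  B <- ds$beta$beta
  ps <- vapply(seq_len(nrow(B)), function(i)
    stats::t.test(B[i, grp == "case"], B[i, grp == "control"],
                  var.equal = TRUE)$p.value, numeric(1))
  frac <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("mosaic mask size and boundary fractions behave as specified", {
  ds <- generate_dataset(sim_params(n_probes = 1200, n_signature = 429,
                                    n_dmrs = 0, seed = 2))
  mos <- generate_mosaic_sample(ds, fraction = 0.28, seed = 5)
  expect_equal(sum(mos$mask), round(0.28 * 429))  # 120
  expect_named(mos$mask, ds$truth$signature$probe_id)

  m0 <- generate_mosaic_sample(ds, 0, seed = 1)
  expect_equal(sum(m0$mask), 0)
  m1 <- generate_mosaic_sample(ds, 1, seed = 1)
  expect_equal(sum(m1$mask), 429)
  # fraction-1 sample sits at case-shifted levels, fraction-0 at control
  sig <- ds$truth$signature
  co <- ds$samples$sample_id[ds$samples$group == "control"]
  ctrl_mean <- rowMeans(ds$beta$beta[sig$probe_id, co])
  expect_lt(mean(abs(m0$beta[sig$probe_id] - ctrl_mean)), 0.05)
  expect_lt(abs(mean(abs(m1$beta[sig$probe_id] - ctrl_mean)) - 0.15), 0.04)

  expect_error(generate_mosaic_sample(ds, 1.2), "fraction")
})

test_that("reference panel matches the mixing profiles exactly", {
  p <- sim_params(n_probes = 1500, n_signature = 30, n_dmrs = 0, seed = 4)
  ds <- generate_dataset(p)
  pan <- generate_reference_panel(p)
  expect_identical(pan$panel$cell_types, p$celltypes)
  expect_lt(max(abs(t(pan$panel$reference) -
                    ds$profiles[pan$panel$marker_probes, ])), 1e-12)
  pan2 <- generate_reference_panel(p)
  expect_identical(pan$panel$reference, pan2$panel$reference)
})

test_that("two-cell-type panels are separable at marker probes", {
  p <- sim_params(n_probes = 600, n_signature = 10, n_dmrs = 0,
                  n_celltypes = 2, seed = 9)
  pan <- generate_reference_panel(p)
  sep <- apply(abs(pan$panel$reference[1, , drop = FALSE] -
                   pan$panel$reference[2, , drop = FALSE]), 1, max)
  expect_gte(max(sep), 0.5)
})

test_that("true cell proportions are simplex rows and infeasible layouts error", {
  ds <- small_sim(seed = 3)
  expect_equal(unname(rowSums(ds$truth$true_proportions)),
               rep(1, nrow(ds$truth$true_proportions)))
  expect_error(sim_params(n_probes = 20, n_signature = 10, n_dmrs = 5,
                          dmr_len = 6), "infeasible")
  expect_error(sim_params(n_probes = 100, n_signature = 8, n_dmrs = 2,
                          dmr_len = 6), "infeasible")
  expect_error(sim_params(dmr_len = 3), "dmr_len")
})

test_that("manifest artifacts occur at the configured rates", {
  ds <- generate_dataset(sim_params(n_probes = 5000, n_signature = 50,
                                    n_dmrs = 0, seed = 6))
  lab <- table(ds$truth$artifact_labels$artifact)
  expect_equal(unname(lab["sex_chrom"]), round(0.02 * 5000))
  expect_equal(unname(lab["snp"]), round(0.02 * 5000))
  expect_equal(unname(lab["non_cpg"]), round(0.002 * 5000))
  # flagged probes carry the matching manifest attributes
  man <- ds$manifest
  snp_ids <- ds$truth$artifact_labels$probe_id[
    ds$truth$artifact_labels$artifact == "snp"]
  expect_true(all(man$snp_maf[match(snp_ids, man$probe_id)] > 0.01))
  sex_ids <- ds$truth$artifact_labels$probe_id[
    ds$truth$artifact_labels$artifact == "sex_chrom"]
  expect_true(all(man$chrom[match(sex_ids, man$probe_id)] %in% c("chrX", "chrY")))
})
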