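make_design <- function(n_case = 8, n_control = 23, seed = 1) {
  set.seed(seed)
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:(n_case + n_control)),
                      group = c(rep("case", n_case), rep("control", n_control)),
                      age = runif(n_case + n_control, 4, 18),
                      sex = rbinom(n_case + n_control, 1, 0.5))
  build_design(validate_sample_sheet(sheet),
               monocyte = runif(n_case + n_control, 0.05, 0.15))
}

test_that("a noise-free probe is fit exactly", {
  X <- make_design()
  y <- 0.5 + 0.2 * X[, "group"]
  B <- matrix(y, nrow = 1, dimnames = list("cg1", rownames(X)))
  fit <- fit_probe_models(B, X)
  expect_equal(unname(fit$b), 0.2, tolerance = 1e-12)
  expect_equal(unname(fit$s2), 0, tolerance = 1e-20)
  expect_equal(fit$d, nrow(X) - ncol(X))
})

test_that("statistics are invariant to a consistent sample permutation", {
  X <- make_design(seed = 2)
  set.seed(3)
  B <- matrix(runif(20 * nrow(X), 0.2, 0.8), 20,
              dimnames = list(sprintf("cg%02d", 1:20), rownames(X)))
  fit <- fit_probe_models(B, X)
  perm <- sample(nrow(X))
  fit_p <- fit_probe_models(B[, perm], X[perm, ])
  expect_equal(fit$b, fit_p$b, tolerance = 1e-12)
  expect_equal(fit$s2, fit_p$s2, tolerance = 1e-12)
})

test_that("OLS group effects are unbiased over 1000 simulated probes", {
  X <- make_design(seed = 4)
  set.seed(5)
  n <- nrow(X)
  B <- matrix(0.4 + rep(0.1, 1000) %o% X[, "group"] + rnorm(1000 * n, 0, 0.03),
              1000, n, dimnames = list(sprintf("cg%04d", 1:1000), rownames(X)))
  fit <- fit_probe_models(B, X)
  expect_lt(abs(mean(fit$b) - 0.1), 0.01)
})

test_that("collinear designs are rejected with the offending columns", {
  sheet <- validate_sample_sheet(
    data.frame(sample_id = paste0("s", 1:6),
               group = rep(c("case", "control"), 3),
               age = c(4, 5, 6, 7, 8, 9), sex = rep(0, 6)))
  # monocyte proportional to age -> collinear with it
  expect_error(build_design(sheet, monocyte = sheet$age / 100),
               "collinear.*age~monocyte")
})

test_that("homogeneous variances are left unshrunk (s2_tilde = s2)", {
  s2 <- rep(0.01, 50)
  mod <- moderate_variances(s2, d = 26)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_tilde, s2, tolerance = 1e-12)
  # and the moderated t equals the ordinary t with inflated df
  b <- seq(-0.1, 0.1, length.out = 50)
  mod2 <- moderate_variances(s2, 26, b = b, stdev_unscaled = 0.4)
  expect_equal(mod2$t_mod, b / (0.4 * sqrt(s2)), tolerance = 1e-12)
})

test_that("injected prior limits behave exactly", {
  set.seed(6)
  s2 <- 0.01 * rchisq(100, 26) / 26
  lim_inf <- moderate_variances(s2, 26, d0 = Inf, s0_2 = 0.012)
  expect_equal(unname(lim_inf$s2_tilde), rep(0.012, 100))
  lim0 <- moderate_variances(s2, 26, d0 = 0)
  expect_equal(lim0$s2_tilde, s2, tolerance = 1e-12)
  expect_error(moderate_variances(rep(0, 100), 26), "zero")
  expect_error(moderate_variances(s2[1:5], 26), ">= 10")
})

test_that("moderation matches limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  X <- make_design(seed = 7)
  set.seed(8)
  n <- nrow(X)
  # heterogeneous variances so the prior is informative
  sds <- sqrt(0.01 * 4 / rchisq(300, 4))
  B <- matrix(0.5 + rnorm(300 * n, 0, rep(sds, n)), 300, n,
              dimnames = list(sprintf("cg%04d", 1:300), rownames(X)))
  fit <- fit_probe_models(B, X)
  mod <- moderate_variances(fit$s2, fit$d, b = fit$b,
                            stdev_unscaled = fit$stdev_unscaled)
  lf <- limma::eBayes(limma::lmFit(B, X))
  expect_equal(mod$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$s2_tilde), unname(lf$s2.post), tolerance = 1e-8)
  expect_equal(unname(mod$t_mod), unname(lf$t[, "group"]), tolerance = 1e-8)
  expect_equal(unname(mod$p), unname(lf$p.value[, "group"]), tolerance = 1e-8)
})

test_that("BH adjustment reproduces the textbook step-up and edge cases", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(9)
  for (i in 1:200) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("signature selection applies strict thresholds and tie-breaks", {
  stats <- data.frame(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE"),
    p_adj = c(0.04, 0.05, 0.01, 0.01, 0.001),
    delta_beta = c(0.09, 0.2, -0.15, 0.30, 0.10))
  # cgA fails |db| (0.09 <= 0.10); cgB fails p (0.05 not < 0.05);
  # cgE fails |db| (0.10 not > 0.10); cgD before cgC (larger |db| at tied p)
  expect_identical(select_signature(stats), c("cgD", "cgC"))
  expect_warning(out <- select_signature(stats, alpha = 0), "empty signature")
  expect_length(out, 0)
})

test_that("the moderated pipeline is calibrated under the null", {
  # fully null: no planted effect and no group composition shift
  p <- sim_params(n_probes = 2000, n_signature = 50, effect_delta = 0,
                  n_dmrs = 0, dirichlet_case = rep(25, 6),
                  dirichlet_control = rep(25, 6), seed = 12)
  ds <- generate_dataset(p)
  pan <- generate_reference_panel(p)
  props <- estimate_proportions_all(ds$beta, pan$panel)
  dm <- run_diffmeth(ds$beta, ds$samples, mono_of(props, ds$samples))
  frac <- mean(dm$stats$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(dm$stats))
  expect_lt(frac, 0.05 + 4 * se)
  expect_warning(select_signature(dm$stats), "empty signature")
})

test_that("scaled-F hyperparameters are recovered by the moment fit", {
  set.seed(13)
  d0 <- 4; s0 <- 0.01; d <- 26
  s2 <- s0 * (rchisq(50000, d) / d) / (rchisq(50000, d0) / d0)
  mod <- moderate_variances(s2, d)
  expect_lt(abs(mod$d0 - d0) / d0, 0.15)
  expect_lt(abs(mod$s0_2 - s0) / s0, 0.10)
})
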