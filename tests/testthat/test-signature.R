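toy_model <- function() {
  # antipodal 3-probe profiles
  beta <- cbind(ca1 = c(0.8, 0.2, 0.6), ca2 = c(0.8, 0.2, 0.6),
                co1 = c(0.2, 0.8, 0.4), co2 = c(0.2, 0.8, 0.4))
  rownames(beta) <- c("cgA", "cgB", "cgC")
  build_reference_profiles(beta, c("cgA", "cgB", "cgC"),
                           c("ca1", "ca2"), c("co1", "co2"))
}

test_that("profiles are per-probe group medians with min-max ranges", {
  beta <- cbind(c1 = c(0.2, 0.1), c2 = c(0.4, 0.3), c3 = c(0.6, 0.5),
                k1 = c(0.5, 0.5), k2 = c(0.7, 0.9))
  rownames(beta) <- c("cgA", "cgB")
  m <- build_reference_profiles(beta, c("cgA", "cgB"),
                                c("c1", "c2", "c3"), c("k1", "k2"))
  expect_equal(unname(m$case_profile), c(0.4, 0.3))
  expect_equal(unname(m$case_range[, "cgA"]), c(0.2, 0.6))
  # even group size uses the midpoint median
  expect_equal(unname(m$control_profile), c(0.6, 0.7))
  # matches an independent sort-based median oracle
  expect_equal(unname(m$case_profile),
               unname(apply(beta[, 1:3], 1, median_oracle)))
})

test_that("antipodal profiles give score 2 for a case and -2 for a control", {
  m <- toy_model()
  sc <- score_sample(c(cgA = 0.8, cgB = 0.2, cgC = 0.6), m)
  expect_equal(sc$r_case, 1)
  expect_equal(sc$r_control, -1)
  expect_equal(sc$score, 2)
  expect_equal(sc$label, "pathogenic")
  sk <- score_sample(c(cgA = 0.2, cgB = 0.8, cgC = 0.4), m)
  expect_equal(sk$score, -2)
  expect_equal(sk$label, "benign")
})

test_that("degenerate scoring inputs are refused", {
  beta <- cbind(ca1 = 0.7, ca2 = 0.8, co1 = 0.2, co2 = 0.3)
  rownames(beta) <- "cgA"
  m1 <- build_reference_profiles(beta, "cgA", c("ca1", "ca2"), c("co1", "co2"))
  expect_s3_class(m1, "signature_model")
  expect_error(score_sample(c(cgA = 0.5), m1), ">= 3 probes")
  m <- toy_model()
  expect_error(score_sample(c(cgA = 0.5, cgB = 0.5, cgC = 0.5), m),
               "zero variance")
  expect_error(score_sample(c(cgA = 0.5, cgB = NA, cgC = NA), m), "missing")
})

test_that("swapping profiles negates every score (antisymmetry)", {
  set.seed(1)
  m <- toy_model()
  swapped <- m
  swapped$case_profile <- m$control_profile
  swapped$control_profile <- m$case_profile
  for (i in 1:20) {
    y <- runif(3); names(y) <- m$probes
    if (sd(y) == 0) next
    expect_equal(score_sample(y, swapped)$score,
                 -score_sample(y, m)$score, tolerance = 1e-12)
  }
})

test_that("scores are invariant to affine transforms of the sample", {
  set.seed(2)
  m <- toy_model()
  y <- c(cgA = 0.7, cgB = 0.3, cgC = 0.55)
  base <- score_sample(y, m)$score
  for (i in 1:10) {
    a <- runif(1, 0.1, 1); b <- runif(1, -0.1, 0.1)
    z <- pmin(pmax(a * y + b, 0), 1)
    if (sd(z) == 0) next
    # keep the transform inside [0,1] so it stays a valid beta vector
    if (any(z != a * y + b)) next
    expect_equal(score_sample(z, m)$score, base, tolerance = 1e-12)
  }
})

test_that("signature model JSON serialization round-trips", {
  m <- toy_model()
  f <- tempfile(fileext = ".json")
  write_signature_model(m, f)
  back <- read_signature_model(f)
  expect_equal(back$probes, m$probes)
  expect_equal(back$case_profile, m$case_profile)
  expect_equal(unname(back$control_range), unname(m$control_range))
})

test_that("classifier evaluation counts the confusion matrix correctly", {
  truth <- c(rep("pathogenic", 8), rep("benign", 94))
  ev <- evaluate_classifier(truth, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  pred <- truth; pred[9] <- "pathogenic"  # one control misclassified
  ev2 <- evaluate_classifier(pred, truth)
  expect_equal(ev2$specificity, 93 / 94)
  expect_equal(ev2$sensitivity, 1)
  expect_warning(ev3 <- evaluate_classifier(rep("benign", 3), rep("benign", 3)),
                 "sensitivity undefined")
  expect_true(is.na(ev3$sensitivity))
  expect_error(evaluate_classifier("maybe", "benign"), "labels")
})

test_that("Euclidean clustering separates shifted clouds, merges duplicates", {
  set.seed(3)
  base <- matrix(runif(40, 0.3, 0.5), 10, 4)
  shifted <- base[, 1:3] + 0.3
  beta <- cbind(base, shifted)
  colnames(beta) <- paste0("s", 1:7)
  rownames(beta) <- paste0("cg", 1:10)
  cl <- cluster_samples(beta)
  expect_equal(length(unique(cl$clusters[1:4])), 1)
  expect_equal(length(unique(cl$clusters[5:7])), 1)
  expect_false(cl$clusters[1] == cl$clusters[5])

  dup <- cbind(beta[, c(1, 1)], beta[, 5, drop = FALSE])
  colnames(dup) <- c("a", "b", "c")
  cl2 <- cluster_samples(dup)
  expect_equal(min(cl2$hclust$height), 0)
})

test_that("replicate-level noise moves scores by less than 0.01", {
  ds <- small_sim(seed = 21)
  sig <- ds$truth$signature$probe_id
  ca <- ds$samples$sample_id[ds$samples$group == "case"]
  co <- ds$samples$sample_id[ds$samples$group == "control"]
  m <- build_reference_profiles(ds$beta$beta, sig, ca, co)
  set.seed(22)
  for (s in c(ca[1], co[1])) {
    y <- ds$beta$beta[sig, s]
    noisy <- plogis(qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6)) +
                    rnorm(length(y), 0, 0.01))
    names(noisy) <- sig
    expect_lt(abs(score_sample(noisy, m)$score - score_sample(y, m)$score),
              0.01)
  }
})
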