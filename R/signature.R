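#' Build median reference profiles and per-group ranges
#'
#' At each signature CpG, the case profile is the median beta across
#' derivation cases and the control profile the median across
#' derivation controls (midpoint median for even group sizes); the
#' per-group \[min, max\] beta ranges support the range-overlap
#' decomposition of partial signatures.
#'
#' @param beta probes x samples matrix (or [beta_matrix()]) covering
#'   all signature probes
#' @param signature_probes ordered signature probe ids
#' @param case_ids,control_ids derivation sample ids (>= 2 each)
#' @return a `signature_model`: `probes`, `case_profile`,
#'   `control_profile`, `case_range`/`control_range` (2 x probes
#'   matrices, rows min/max), `threshold` (0)
#' @export
build_reference_profiles <- function(beta, signature_probes,
                                     case_ids, control_ids) {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  if (length(signature_probes) == 0) stop("empty signature")
  if (length(case_ids) < 2 || length(control_ids) < 2)
    stop("need >= 2 samples per derivation group")
  missing <- setdiff(signature_probes, rownames(beta))
  if (length(missing) > 0)
    stop("signature probes missing from beta: ",
         paste(utils::head(missing, 5), collapse = ", "))
  bc <- beta[signature_probes, case_ids, drop = FALSE]
  bk <- beta[signature_probes, control_ids, drop = FALSE]
  rng <- function(m) apply(m, 1, range)  # 2 x probes: min, max
  model <- list(probes = signature_probes,
                case_profile = apply(bc, 1, stats::median),
                control_profile = apply(bk, 1, stats::median),
                case_range = rng(bc),
                control_range = rng(bk),
                threshold = 0)
  structure(model, class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d CpGs, decision threshold %g\n",
              length(x$probes), x$threshold))
  invisible(x)
}

#' Serialize a signature model to JSON
#' @param model a `signature_model`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(probes = model$probes,
              case_profile = unname(model$case_profile),
              control_profile = unname(model$control_profile),
              case_min = unname(model$case_range[1, ]),
              case_max = unname(model$case_range[2, ]),
              control_min = unname(model$control_range[1, ]),
              control_max = unname(model$control_range[2, ]),
              threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model from JSON
#' @param path JSON file written by [write_signature_model()]
#' @return a `signature_model`
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- obj$probes
  named <- function(v) stats::setNames(as.numeric(v), pr)
  structure(list(probes = pr,
                 case_profile = named(obj$case_profile),
                 control_profile = named(obj$control_profile),
                 case_range = rbind(named(obj$case_min), named(obj$case_max)),
                 control_range = rbind(named(obj$control_min),
                                       named(obj$control_max)),
                 threshold = obj$threshold),
            class = "signature_model")
}

#' Score a query sample against the signature model
#'
#' The episignature score is the difference of Pearson correlations of
#' the sample's signature-site beta vector with the case and control
#' median profiles:
#' \deqn{score = r(B_{sig}, case\ profile) - r(B_{sig}, control\ profile)}
#' A positive score classifies the sample as "pathogenic", a negative
#' one as "benign"; a score of exactly 0 is labeled "benign" with a
#' boundary warning.
#'
#' @param sample_beta named beta vector covering the signature probes
#'   (pairwise-complete correlation is used when >= 90% of probes are
#'   present; more missingness is an error)
#' @param model a `signature_model` from [build_reference_profiles()]
#' @return list: `r_case`, `r_control`, `score`, `label`
#' @export
score_sample <- function(sample_beta, model) {
  stopifnot(inherits(model, "signature_model"))
  if (length(model$probes) < 3)
    stop("signature too short to correlate (need >= 3 probes)")
  y <- sample_beta[model$probes]
  ok <- !is.na(y)
  if (mean(ok) < 0.9)
    stop("more than 10% of signature probes missing from sample")
  y <- y[ok]
  cp <- model$case_profile[ok]
  kp <- model$control_profile[ok]
  if (stats::sd(y) == 0)
    stop("undefined correlation: sample has zero variance at signature probes")
  if (stats::sd(cp) == 0 || stats::sd(kp) == 0)
    stop("undefined correlation: reference profile has zero variance")
  r_case <- stats::cor(y, cp)
  r_control <- stats::cor(y, kp)
  score <- r_case - r_control
  if (score == model$threshold)
    warning("score exactly at the decision boundary; labeling 'benign'")
  list(r_case = r_case, r_control = r_control, score = score,
       label = if (score > model$threshold) "pathogenic" else "benign")
}

#' Score every sample of a beta matrix
#'
#' @param beta probes x samples matrix (or [beta_matrix()])
#' @param model a `signature_model`
#' @return data frame: sample_id, r_case, r_control, score, label
#' @export
score_samples <- function(beta, model) {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  rows <- lapply(colnames(beta), function(s) {
    sc <- score_sample(beta[, s], model)
    data.frame(sample_id = s, r_case = sc$r_case, r_control = sc$r_control,
               score = sc$score, label = sc$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate classifications against truth labels
#'
#' @param labels predicted labels ("pathogenic"/"benign")
#' @param truth true labels ("pathogenic"/"benign")
#' @return list: `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), and the `confusion` counts (tp, fn, tn, fp); an empty
#'   truth class yields NA for the corresponding metric with a warning.
#' @export
evaluate_classifier <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  bad <- setdiff(unique(c(labels, truth)), c("pathogenic", "benign"))
  if (length(bad) > 0)
    stop("labels must be 'pathogenic' or 'benign'; got: ",
         paste(bad, collapse = ", "))
  tp <- sum(labels == "pathogenic" & truth == "pathogenic")
  fn <- sum(labels == "benign" & truth == "pathogenic")
  tn <- sum(labels == "benign" & truth == "benign")
  fp <- sum(labels == "pathogenic" & truth == "benign")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no pathogenic samples in truth: sensitivity undefined"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no benign samples in truth: specificity undefined"); NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Hierarchical clustering of samples at the signature probes
#'
#' Agglomerative clustering on Euclidean distances between the
#' samples' signature-site beta vectors, with a 2-cluster cut.
#'
#' @param beta probes x samples matrix (or [beta_matrix()]) restricted
#'   or restrictable to the signature probes
#' @param signature_probes probe ids to cluster on (default: all rows)
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   "complete")
#' @return list: `hclust` (the dendrogram object), `clusters` (named
#'   2-cut labels in 1/2)
#' @export
cluster_samples <- function(beta, signature_probes = NULL,
                            linkage = "complete") {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  if (!is.null(signature_probes))
    beta <- beta[signature_probes, , drop = FALSE]
  if (ncol(beta) < 2) stop("need >= 2 samples to cluster")
  hc <- stats::hclust(stats::dist(t(beta), method = "euclidean"),
                      method = linkage)
  list(hclust = hc, clusters = stats::cutree(hc, k = 2))
}
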