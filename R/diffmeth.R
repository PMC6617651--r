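#' Build the covariate-adjusted design matrix
#'
#' Columns: intercept, group indicator (case = 1), age, sex, and
#' estimated monocyte proportion — the covariates of the published
#' regression model.
#'
#' @param sheet validated sample sheet rows for the modeled samples
#' @param monocyte numeric vector of estimated monocyte proportions
#'   aligned with `sheet`
#' @return numeric design matrix with rownames = sample ids
#' @export
build_design <- function(sheet, monocyte) {
  if (nrow(sheet) != length(monocyte))
    stop("monocyte vector must align with sample sheet rows")
  X <- cbind(intercept = 1,
             group = as.numeric(sheet$group == "case"),
             age = sheet$age,
             sex = sheet$sex,
             monocyte = monocyte)
  rownames(X) <- sheet$sample_id
  if (qr(X)$rank < ncol(X)) {
    cors <- suppressWarnings(stats::cor(X[, -1]))
    diag(cors) <- 0
    bad <- which(abs(cors) > 0.999, arr.ind = TRUE)
    msg <- if (nrow(bad) > 0)
      paste(unique(apply(bad, 1, function(ij)
        paste(sort(colnames(cors)[ij]), collapse = "~"))), collapse = ", ")
      else "unknown columns"
    stop("rank-deficient design; collinear: ", msg)
  }
  X
}

#' Per-probe ordinary least squares against a design matrix
#'
#' Fits every probe's beta values on the design in one pass. `b` is the
#' coefficient of `coef_name` (the group indicator by default), `s2`
#' the residual mean square on `d = n - rank` degrees of freedom, and
#' `stdev_unscaled` the unscaled standard error of `b` (so
#' `se = stdev_unscaled * sqrt(s2)`).
#'
#' @param beta probes x samples matrix (rows with any NA are dropped
#'   and reported in the `dropped` element)
#' @param design full-rank design matrix, rows aligned with samples
#' @param coef_name name of the coefficient of interest
#' @return list: `b`, `s2`, `d`, `stdev_unscaled`, `coefficients`
#'   (all columns), `fitted`, `residuals`, `dropped`
#' @export
fit_probe_models <- function(beta, design, coef_name = "group") {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (ncol(beta) != nrow(design))
    stop("design rows must match beta columns")
  qrX <- qr(design)
  if (qrX$rank < ncol(design))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(design)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  n <- nrow(design)
  d <- n - qrX$rank
  if (d < 1) stop("need more samples than design columns")
  if (!coef_name %in% colnames(design))
    stop("coefficient not in design: ", coef_name)

  complete <- rowSums(is.na(beta)) == 0
  dropped <- rownames(beta)[!complete]
  B <- beta[complete, , drop = FALSE]

  coefs <- t(qr.coef(qrX, t(B)))             # probes x covariates
  fitted <- coefs %*% t(design)
  resid <- B - fitted
  s2 <- rowSums(resid^2) / d
  xtxinv <- chol2inv(qr.R(qrX))
  dimnames(xtxinv) <- list(colnames(design), colnames(design))
  su <- sqrt(xtxinv[coef_name, coef_name])

  list(b = coefs[, coef_name], s2 = s2, d = d,
       stdev_unscaled = su, coefficients = coefs,
       fitted = fitted, residuals = resid, dropped = dropped)
}

# Newton inversion of the trigamma function (monotone decreasing on
# (0, Inf)); used to solve trigamma(d0/2) = excess log-variance spread.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Fits the scaled-F prior \eqn{s^2 \sim s_0^2 F(d, d_0)} by matching
#' the first two moments of \eqn{\log s^2}: the prior degrees of
#' freedom d0 solve a trigamma equation (numeric inversion), and the
#' prior variance s0^2 follows from the mean. Posterior variances
#' shrink toward the prior, \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) /
#' (d_0 + d)}, and the moderated t uses d0 + d degrees of freedom. If
#' the moment estimate of d0 is nonpositive or nonfinite (log-variance
#' spread no larger than sampling noise), d0 is set to infinity and all
#' moderated variances equal s0^2.
#'
#' @param s2 per-probe residual variances (>= 10 values)
#' @param d residual degrees of freedom (shared across probes)
#' @param b optional per-probe coefficients; with `stdev_unscaled`,
#'   moderated t and two-sided p-values are returned
#' @param stdev_unscaled unscaled standard error of `b`
#' @param d0,s0_2 optional fixed prior hyperparameters; when supplied
#'   the moment estimation is skipped (d0 = 0 recovers the ordinary t,
#'   d0 = Inf the fully pooled prior-dominant limit)
#' @return list: `d0`, `s0_2`, `s2_tilde`, and (when `b` is supplied)
#'   `t_mod`, `p`, `df_total`
#' @export
moderate_variances <- function(s2, d, b = NULL, stdev_unscaled = NULL,
                               d0 = NULL, s0_2 = NULL) {
  if (length(s2) < 10) stop("need >= 10 probes to moderate variances")
  if (d < 1) stop("residual degrees of freedom must be >= 1")
  if (all(s2 <= 0)) stop("moderation error: all residual variances are zero")

  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  if (is.null(d0)) {
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # spread of log s2 no larger than sampling noise: degenerate
      # prior; pooled mean variance is the MLE of the scale
      d0 <- Inf
      s0_2 <- mean(s2[pos])
    }
  } else if (is.null(s0_2)) {
    s0_2 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else mean(s2[pos])
  }
  if (!is.finite(d0)) {
    s2_tilde <- rep(s0_2, length(s2))
  } else {
    s2_tilde <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  names(s2_tilde) <- names(s2)
  out <- list(d0 = d0, s0_2 = s0_2, s2_tilde = s2_tilde)
  if (!is.null(b)) {
    if (is.null(stdev_unscaled)) stop("stdev_unscaled required with b")
    t_mod <- b / (stdev_unscaled * sqrt(s2_tilde))
    df_total <- d0 + d
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    out$t_mod <- t_mod
    out$p <- p
    out$df_total <- df_total
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; ties preserved; output
#' order matches input order.
#'
#' @param p p-values in \[0,1\]
#' @return adjusted p-values
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Raw-scale group difference of mean beta
#'
#' delta beta = mean(case beta) - mean(control beta), the unadjusted
#' "10% methylation difference" scale (the adjusted model coefficient
#' is reported alongside in [run_diffmeth()]).
#'
#' @param beta probes x samples matrix
#' @param case_ids,control_ids sample id vectors
#' @return named per-probe delta beta
#' @export
delta_beta <- function(beta, case_ids, control_ids) {
  rowMeans(beta[, case_ids, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, control_ids, drop = FALSE], na.rm = TRUE)
}

#' Covariate-adjusted differential methylation table
#'
#' OLS per probe, empirical-Bayes variance moderation, two-sided
#' moderated-t p-values, BH adjustment, and raw delta beta.
#'
#' @param bm a [beta_matrix()]
#' @param sheet validated sample sheet (all rows are modeled; apply the
#'   age filter upstream)
#' @param monocyte estimated monocyte proportion per sample, aligned
#'   with `sheet`
#' @return list with `stats` (data frame: probe_id, b, s2, d, s2_tilde,
#'   t_mod, p, p_adj, delta_beta), `d0`, `s0_2`, `design`, `fit`
#' @export
run_diffmeth <- function(bm, sheet, monocyte) {
  stopifnot(inherits(bm, "beta_matrix"))
  keep <- sheet$group %in% c("case", "control")
  sheet <- sheet[keep, , drop = FALSE]
  monocyte <- monocyte[keep]
  bmat <- bm$beta[, sheet$sample_id, drop = FALSE]
  design <- build_design(sheet, monocyte)
  fit <- fit_probe_models(bmat, design)
  mod <- moderate_variances(fit$s2, fit$d, b = fit$b,
                            stdev_unscaled = fit$stdev_unscaled)
  p_adj <- adjust_bh(mod$p)
  db <- delta_beta(bmat, sheet$sample_id[sheet$group == "case"],
                   sheet$sample_id[sheet$group == "control"])
  used <- setdiff(rownames(bmat), fit$dropped)
  stats <- data.frame(probe_id = used,
                      b = fit$b, s2 = fit$s2, d = fit$d,
                      s2_tilde = mod$s2_tilde, t_mod = mod$t_mod,
                      p = mod$p, p_adj = p_adj,
                      delta_beta = db[used],
                      stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  list(stats = stats, d0 = mod$d0, s0_2 = mod$s0_2,
       design = design, fit = fit)
}

#' Select the DNAm signature from a differential-methylation table
#'
#' Keeps probes with BH-adjusted p strictly below `alpha` AND
#' |delta beta| strictly above `min_abs_delta`; ordered by adjusted p,
#' then |delta beta| descending, then probe id.
#'
#' @param stats data frame with `probe_id`, `p_adj`, `delta_beta`
#' @param alpha adjusted-p cutoff (default 0.05)
#' @param min_abs_delta |delta beta| cutoff (default 0.10)
#' @return character vector of signature probe ids (possibly empty,
#'   with a warning)
#' @export
select_signature <- function(stats, alpha = 0.05, min_abs_delta = 0.10) {
  hit <- stats$p_adj < alpha & abs(stats$delta_beta) > min_abs_delta
  sel <- stats[hit, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("empty signature: no probe passed p_adj < ", alpha,
            " and |delta beta| > ", min_abs_delta)
    return(character(0))
  }
  ord <- order(sel$p_adj, -abs(sel$delta_beta), sel$probe_id)
  sel$probe_id[ord]
}
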