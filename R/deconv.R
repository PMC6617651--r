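#' Construct a cell-type reference panel
#'
#' @param cell_types character vector of >= 2 cell-type names
#' @param marker_probes unique marker probe ids
#' @param reference matrix of mean beta, cell types x marker probes
#' @return a `celltype_panel`
#' @export
celltype_panel <- function(cell_types, marker_probes, reference) {
  if (length(cell_types) < 2) stop("need >= 2 cell types")
  if (anyDuplicated(marker_probes)) stop("marker probes must be unique")
  reference <- as.matrix(reference)
  if (nrow(reference) != length(cell_types) ||
      ncol(reference) != length(marker_probes))
    stop("reference must be cell types x marker probes")
  if (any(reference < 0 | reference > 1, na.rm = TRUE))
    stop("reference beta values must lie in [0,1]")
  dimnames(reference) <- list(cell_types, marker_probes)
  structure(list(cell_types = cell_types, marker_probes = marker_probes,
                 reference = reference),
            class = "celltype_panel")
}

#' Select cell-type discriminating probes from sorted-cell data
#'
#' For each cell type, ranks probes by the one-vs-rest two-sample t
#' statistic and keeps the `n_per_type/2` most hypermethylated and
#' `n_per_type/2` most hypomethylated probes; the union across types is
#' returned (the Houseman-style marker selection).
#'
#' @param source_beta probes x samples beta matrix of sorted cells
#' @param labels cell-type label per sample (>= 2 samples per type)
#' @param n_per_type markers per cell type; must be even
#' @return character vector of selected marker probe ids
#' @export
select_discriminating_probes <- function(source_beta, labels, n_per_type = 50L) {
  if (n_per_type %% 2 != 0) stop("n_per_type must be even")
  labels <- as.character(labels)
  if (ncol(source_beta) != length(labels))
    stop("labels must match source_beta columns")
  if (any(table(labels) < 2)) stop("need >= 2 sorted samples per cell type")
  types <- unique(labels)
  sel <- character(0)
  tmax <- 0
  for (ty in types) {
    g <- labels == ty
    t_stat <- row_t_stat(source_beta[, g, drop = FALSE],
                         source_beta[, !g, drop = FALSE])
    t_stat[is.nan(t_stat)] <- 0  # 0/0: no difference, no variance
    tmax <- max(tmax, max(abs(t_stat)))
    ord <- order(t_stat)
    lo <- rownames(source_beta)[ord[seq_len(n_per_type / 2)]]
    hi <- rownames(source_beta)[rev(ord)[seq_len(n_per_type / 2)]]
    sel <- union(sel, c(hi, lo))
  }
  if (tmax < 1e-8)
    warning("cell types are indistinguishable: all |t| ~ 0, selection arbitrary")
  sel
}

# equal-variance two-sample t per row; x, y matrices with same rows
row_t_stat <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  (mx - my) / sqrt(sp * (1 / nx + 1 / ny))
}

#' Estimate cell-type proportions for one sample
#'
#' Solves the constrained least-squares projection
#' \eqn{\min_c \|y - R^T c\|^2} subject to \eqn{c \ge 0} and
#' \eqn{\sum c \le 1}, where R is the panel reference — the
#' reference-based (Houseman-style) deconvolution. The inequality on
#' the sum (rather than equality) leaves room for unmodeled cell types;
#' the residual mass `1 - sum(c)` and the fit residual norm are
#' reported.
#'
#' @param sample_beta named beta vector covering the panel's marker
#'   probes (up to 20% may be missing)
#' @param panel a [celltype_panel()]
#' @return list with `proportions` (named, >= 0, sum <= 1),
#'   `residual_norm`, and `unexplained` (1 - sum of proportions).
#' @export
estimate_proportions <- function(sample_beta, panel) {
  stopifnot(inherits(panel, "celltype_panel"))
  y <- sample_beta[panel$marker_probes]
  ok <- !is.na(y)
  if (mean(ok) < 0.8)
    stop("estimation error: >20% of marker probes missing from sample")
  A <- t(panel$reference[, ok, drop = FALSE])  # markers x cell types
  y <- y[ok]
  k <- ncol(A)
  D <- crossprod(A)
  d <- crossprod(A, y)
  # ridge jitter keeps D positive definite for collinear references
  D <- D + diag(1e-10 * max(diag(D)), k)
  # constraints: c_i >= 0 (k rows) and -sum(c) >= -1
  Amat <- cbind(diag(k), -rep(1, k))
  bvec <- c(rep(0, k), -1)
  fit <- quadprog::solve.QP(D, d, Amat, bvec)
  c_hat <- pmax(fit$solution, 0)
  names(c_hat) <- panel$cell_types
  res <- sqrt(sum((y - A %*% c_hat)^2))
  list(proportions = c_hat, residual_norm = res,
       unexplained = max(0, 1 - sum(c_hat)))
}

#' Estimate proportions for every sample of a beta matrix
#'
#' @param bm a [beta_matrix()] covering the panel's marker probes
#' @param panel a [celltype_panel()]
#' @return data frame: one row per sample, one column per cell type,
#'   plus `residual_norm` and `unexplained`.
#' @export
estimate_proportions_all <- function(bm, panel) {
  stopifnot(inherits(bm, "beta_matrix"))
  res <- lapply(colnames(bm$beta), function(s) {
    est <- estimate_proportions(bm$beta[, s], panel)
    c(est$proportions, residual_norm = est$residual_norm,
      unexplained = est$unexplained)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(sample_id = colnames(bm$beta), out)
  rownames(out) <- NULL
  out
}

#' Compare estimated cell proportions between groups
#'
#' Equal-variance two-sample t-test (Student's) per cell type,
#' case vs control.
#'
#' @param props data frame from [estimate_proportions_all()]
#' @param groups group per sample ("case"/"control"; other labels are
#'   ignored), aligned with `props` rows
#' @return data frame: cell_type, mean_case, mean_control, t, p
#' @export
compare_cell_proportions <- function(props, groups) {
  if (nrow(props) != length(groups))
    stop("groups must align with proportion rows")
  ca <- groups == "case"; co <- groups == "control"
  if (sum(ca) < 2 || sum(co) < 2)
    stop("need >= 2 samples per group")
  types <- setdiff(names(props), c("sample_id", "residual_norm", "unexplained"))
  rows <- lapply(types, function(ty) {
    x <- props[[ty]][ca]; y <- props[[ty]][co]
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(cell_type = ty, mean_case = mean(x), mean_control = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
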