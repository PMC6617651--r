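#' Construct a validated beta matrix
#'
#' A `beta_matrix` bundles a probes x samples matrix of methylation
#' fractions (beta values, methylated signal / total signal, in \[0,1\])
#' with an optional matrix of per-measurement detection p-values of the
#' same shape. Probe ids are row names, sample ids column names; both
#' must be unique.
#'
#' @param beta numeric matrix of beta values with unique row (probe) and
#'   column (sample) names; all finite values must lie in \[0,1\]. `NA`
#'   encodes missing measurements.
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0,1\], same dimensions and dimnames as `beta`.
#' @return an object of class `beta_matrix` (a list with elements
#'   `beta` and `detection_p`).
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "))
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    culprits <- apply(utils::head(bad, 5), 1, function(ij)
      sprintf("%s/%s=%g", rownames(beta)[ij[1]], colnames(beta)[ij[2]],
              beta[ij[1], ij[2]]))
    stop("beta values outside [0,1] at ", nrow(bad), " cell(s): ",
         paste(culprits, collapse = ", "))
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta)))
      stop("`detection_p` must be a matrix with the same dimensions as `beta`")
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("`detection_p` dimnames must match `beta`")
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values outside [0,1]")
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (+ detection p)"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

probe_ids <- function(bm) rownames(bm$beta)
sample_ids <- function(bm) colnames(bm$beta)

#' Subset a beta matrix by probes and/or samples
#'
#' @param bm a [beta_matrix()]
#' @param probes,samples character vectors of ids (or NULL to keep all)
#' @return a `beta_matrix` restricted to the requested probes/samples,
#'   in the requested order.
#' @export
subset_beta <- function(bm, probes = NULL, samples = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  pr <- if (is.null(probes)) rownames(bm$beta) else probes
  sm <- if (is.null(samples)) colnames(bm$beta) else samples
  missing_p <- setdiff(pr, rownames(bm$beta))
  if (length(missing_p) > 0)
    stop("probes absent from beta matrix: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  missing_s <- setdiff(sm, colnames(bm$beta))
  if (length(missing_s) > 0)
    stop("samples absent from beta matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  beta_matrix(bm$beta[pr, sm, drop = FALSE],
              if (is.null(bm$detection_p)) NULL
              else bm$detection_p[pr, sm, drop = FALSE])
}

#' Read a beta matrix from TSV
#'
#' Expects a tab-separated UTF-8 file with a header row of sample ids and
#' a first column of probe ids (header `probe_id`). "NA" encodes missing.
#'
#' @param path file path of the beta TSV
#' @param detection_path optional path of a detection-p TSV in the same
#'   layout
#' @return a [beta_matrix()]
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2)
    stop("malformed beta file: need a probe id column plus >=1 sample column")
  if (!is.character(dt[[1]]))
    stop("malformed header: first column must hold probe ids")
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed beta file: non-numeric beta values")
  rownames(m) <- dt[[1]]
  dp <- NULL
  if (!is.null(detection_path)) {
    dpdt <- data.table::fread(detection_path, sep = "\t", header = TRUE,
                              data.table = FALSE)
    dp <- as.matrix(dpdt[, -1, drop = FALSE])
    rownames(dp) <- dpdt[[1]]
    dp <- dp[rownames(m), colnames(m), drop = FALSE]
  }
  beta_matrix(m, dp)
}

#' Write a beta matrix to TSV
#'
#' @param bm a [beta_matrix()]
#' @param path output path for the beta TSV
#' @param detection_path optional output path for the detection-p TSV
#' @return invisibly, `path`
#' @export
write_beta_matrix <- function(bm, path, detection_path = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  df <- data.frame(probe_id = rownames(bm$beta), bm$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(detection_path) && !is.null(bm$detection_p)) {
    dpf <- data.frame(probe_id = rownames(bm$detection_p), bm$detection_p,
                      check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(dpf, detection_path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

manifest_required_cols <- c("probe_id", "chrom", "pos", "probe_class",
                            "snp_maf", "cross_reactive", "genes")
probe_classes <- c("CpG", "non-CpG", "control")

#' Validate a probe manifest
#'
#' A manifest is a data frame with one row per probe: `probe_id`,
#' `chrom`, `pos` (1-based, fully closed coordinate of the interrogated
#' cytosine, per the Illumina manifest convention), `probe_class` (one of
#' CpG / non-CpG / control), `snp_maf` (minor-allele frequency of the
#' nearest interfering SNP, 0 if none), `cross_reactive` (0/1 flag) and
#' `genes` (semicolon-separated `SYMBOL:region` annotations, possibly
#' empty). Extra columns are preserved untouched.
#'
#' @param manifest data frame to validate
#' @return the validated manifest (invisibly coerced types)
#' @export
validate_manifest <- function(manifest) {
  miss <- setdiff(manifest_required_cols, names(manifest))
  if (length(miss) > 0)
    stop("manifest missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("duplicate probe_id in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "))
  if (any(manifest$pos < 1)) stop("manifest pos must be >= 1")
  if (any(manifest$snp_maf < 0 | manifest$snp_maf > 0.5))
    stop("snp_maf must lie in [0, 0.5]")
  if (!all(manifest$probe_class %in% probe_classes))
    stop("probe_class must be one of: ", paste(probe_classes, collapse = ", "))
  manifest$cross_reactive <- as.integer(manifest$cross_reactive)
  manifest$genes <- ifelse(is.na(manifest$genes), "", as.character(manifest$genes))
  manifest
}

#' Read a probe manifest from TSV
#' @param path manifest TSV with the columns documented in
#'   [validate_manifest()]
#' @return validated manifest data frame
#' @export
read_manifest <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  validate_manifest(df)
}

#' Write a probe manifest to TSV
#' @param manifest validated manifest data frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(validate_manifest(manifest), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

sample_groups <- c("case", "control", "test")

#' Validate a sample sheet
#'
#' One row per sample: `sample_id`, `group` (case / control / test),
#' `age` in years, `sex` (0/1 covariate code) and optional `replicate_of`.
#'
#' @param sheet data frame to validate
#' @return validated sample sheet
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "group", "age", "sex")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0)
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$group %in% sample_groups))
    stop("unknown group value(s): ",
         paste(unique(setdiff(sheet$group, sample_groups)), collapse = ", "),
         " (allowed: ", paste(sample_groups, collapse = ", "), ")")
  if (any(!is.finite(sheet$age)) || any(sheet$age < 0))
    stop("ages must be finite and nonnegative")
  if (!all(sheet$sex %in% c(0, 1)))
    stop("sex must be coded 0/1")
  if (is.null(sheet$replicate_of)) sheet$replicate_of <- NA_character_
  sheet
}

#' Read a sample sheet from TSV
#' @param path sample sheet TSV
#' @return validated sample sheet data frame
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  validate_sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet validated sample sheet
#' @param path output path
#' @return invisibly, `path`
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(validate_sample_sheet(sheet), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Thresholds mirror the published workflow: signature CpGs require a
#' Benjamini-Hochberg adjusted p < `alpha` (0.05) and |delta beta| >
#' `min_abs_delta` (0.10); signature derivation uses samples older than
#' `min_age` (2 years); DMRs join probes with gaps < `max_gap` (500 bp)
#' and are retained at bootstrap p < `dmr_p` (0.01) with at least
#' `dmr_min_len` (4) CpGs over `n_boot` (1000) bootstrap iterations;
#' probe QC drops probes with detection p > `detection_p_cutoff` (0.01)
#' in any sample and probes with raw beta exactly 0 or 1 in more than
#' `raw_extreme_frac` (0.25%) of samples.
#'
#' @param ... named overrides of any default
#' @return a named list of class `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(alpha = 0.05, min_abs_delta = 0.10, min_age = 2,
              max_gap = 500L, dmr_p = 0.01, dmr_min_len = 4L,
              n_boot = 1000L, detection_p_cutoff = 0.01,
              raw_extreme_frac = 0.0025, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$min_abs_delta >= 0, cfg$min_abs_delta < 1,
            cfg$min_age >= 0,
            cfg$max_gap > 0,
            cfg$dmr_p > 0, cfg$dmr_p <= 1,
            cfg$dmr_min_len >= 1,
            cfg$n_boot >= 1,
            cfg$detection_p_cutoff > 0, cfg$detection_p_cutoff <= 1,
            cfg$raw_extreme_frac >= 0, cfg$raw_extreme_frac < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#' @param path YAML file whose keys mirror [default_config()]
#' @return a validated `pipeline_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
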