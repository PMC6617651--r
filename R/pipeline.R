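#' Run the full signature workflow
#'
#' Executes, in order: probe QC, cell-type deconvolution,
#' covariate-adjusted differential methylation, signature selection,
#' reference-profile scoring, and DMR detection. Signature derivation
#' uses only case/control samples older than `config$min_age` years;
#' all samples (including `test` group) are scored against the
#' resulting model. Any stage failure aborts with the stage name; the
#' partial results accumulated so far are attached to the error
#' condition (`$partial`).
#'
#' @param bm a [beta_matrix()]
#' @param manifest validated probe manifest covering `bm`
#' @param sheet validated sample sheet covering `bm`'s samples
#' @param panel a [celltype_panel()] for deconvolution
#' @param config a [default_config()]
#' @param out_dir optional directory: all result tables are written
#'   there as TSV (model as JSON) plus a structured run log
#' @return a `pipeline_result` list: `qc_report`, `beta` (filtered),
#'   `proportions`, `celltype_tests`, `diffmeth` (stats + d0/s0_2),
#'   `signature`, `model`, `scores`, `evaluation`, `dmr`, `log`,
#'   `config`
#' @export
run_pipeline <- function(bm, manifest, sheet, panel,
                         config = default_config(), out_dir = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  manifest <- validate_manifest(manifest)
  sheet <- validate_sample_sheet(sheet)
  config <- validate_config(config)
  res <- list(config = config)
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail,
      stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      res$log <- do.call(rbind, log)
      stop(structure(class = c("methsig_pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s",
                                            stage, conditionMessage(e)),
                          call = sys.call(-1), partial = res)))
    })
  }

  # 1. probe QC
  qc <- run_stage("qc", apply_probe_filters(bm, manifest, config))
  res$qc_report <- qc$report
  res$beta <- qc$beta
  note("qc", qc$report$n_input, qc$report$n_remaining)

  # 2. cell-type deconvolution (on the unfiltered matrix: marker
  # probes need not survive signature-oriented QC)
  props <- run_stage("celltype", estimate_proportions_all(bm, panel))
  res$proportions <- props
  grp <- sheet$group[match(props$sample_id, sheet$sample_id)]
  res$celltype_tests <- run_stage("celltype",
    compare_cell_proportions(props, grp))
  note("celltype", ncol(bm$beta), nrow(props))

  # 3. differential methylation on derivation samples (age-filtered)
  derivation <- sheet$group %in% c("case", "control") &
    sheet$age > config$min_age
  dsheet <- sheet[derivation, , drop = FALSE]
  mono <- props$Mono[match(dsheet$sample_id, props$sample_id)]
  if (is.null(mono) || anyNA(mono))
    mono <- props[[2]][match(dsheet$sample_id, props$sample_id)]
  dm <- run_stage("diffmeth", run_diffmeth(res$beta, dsheet, mono))
  res$diffmeth <- dm
  note("diffmeth", nrow(res$beta$beta), nrow(dm$stats),
       sprintf("derivation_samples=%d d0=%.3g", nrow(dsheet), dm$d0))

  # 4. signature selection
  sig <- run_stage("signature", suppressWarnings(
    select_signature(dm$stats, config$alpha, config$min_abs_delta)))
  res$signature <- sig
  note("signature", nrow(dm$stats), length(sig))

  # 5. scoring: reference profiles + all-sample scores
  sc <- run_stage("score", {
    if (length(sig) == 0) stop("empty signature")
    model <- build_reference_profiles(
      res$beta, sig,
      case_ids = dsheet$sample_id[dsheet$group == "case"],
      control_ids = dsheet$sample_id[dsheet$group == "control"])
    scores <- score_samples(subset_beta(bm, probes = sig), model)
    list(model = model, scores = scores)
  })
  res$model <- sc$model
  res$scores <- sc$scores
  known <- sheet$group[match(sc$scores$sample_id, sheet$sample_id)] %in%
    c("case", "control")
  truth <- ifelse(sheet$group[match(sc$scores$sample_id,
                                    sheet$sample_id)] == "case",
                  "pathogenic", "benign")
  res$evaluation <- evaluate_classifier(sc$scores$label[known], truth[known])
  note("score", ncol(bm$beta), nrow(sc$scores))

  # 6. DMR detection
  res$dmr <- run_stage("dmr",
    find_dmrs(res$beta, manifest, dsheet, mono, config))
  note("dmr", nrow(res$dmr$candidates), nrow(res$dmr$dmrs))

  res$log <- do.call(rbind, log)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  structure(res, class = "pipeline_result")
}

#' Write all pipeline result tables to a directory
#'
#' @param res a `pipeline_result`
#' @param out_dir output directory (created if absent)
#' @return invisibly, `out_dir`
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    data.table::fwrite(df, file.path(out_dir, name), sep = "\t",
                       na = "NA", quote = FALSE)
  w(res$qc_report$filters, "qc_report.tsv")
  write_beta_matrix(res$beta, file.path(out_dir, "beta_filtered.tsv"))
  w(res$proportions, "proportions.tsv")
  w(res$celltype_tests, "celltype_tests.tsv")
  w(res$diffmeth$stats, "stats.tsv")
  writeLines(res$signature, file.path(out_dir, "signature_probes.txt"))
  if (!is.null(res$model))
    write_signature_model(res$model, file.path(out_dir, "model.json"))
  if (!is.null(res$scores)) w(res$scores, "scores.tsv")
  if (!is.null(res$dmr) && nrow(res$dmr$dmrs) >= 0)
    w(res$dmr$dmrs[, setdiff(names(res$dmr$dmrs), "probes"), drop = FALSE],
      "dmrs.tsv")
  w(res$log, "run_log.tsv")
  yaml::write_yaml(c(unclass(res$config),
                     list(package_version = as.character(
                       utils::packageVersion("methsig")))),
                   file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("methsig pipeline result\n")
  print(x$log, row.names = FALSE)
  cat(sprintf("signature: %d CpGs; DMRs: %d; sensitivity %.3f, specificity %.3f\n",
              length(x$signature), nrow(x$dmr$dmrs),
              x$evaluation$sensitivity, x$evaluation$specificity))
  invisible(x)
}
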