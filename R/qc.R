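#' Apply probe-removal filters to a beta matrix
#'
#' Removes probes in a fixed order, attributing each removal to the
#' first rule it fails (so per-filter counts sum to the removed total):
#' \enumerate{
#'   \item detection-flawed probes — detection p > `detection_p_cutoff`
#'     in at least one sample;
#'   \item probes near common SNPs — `snp_maf` > 0.01;
#'   \item cross-reactive probes;
#'   \item probes with raw beta exactly 0 or 1 in more than
#'     `raw_extreme_frac` of samples;
#'   \item non-CpG probes;
#'   \item X/Y-chromosome probes.
#' }
#' "Detection flaw" is operationalized as detection p above the cutoff
#' in any sample; the rule is recorded in the report metadata.
#'
#' @param bm a [beta_matrix()]; step 1 is skipped (count 0) when it
#'   carries no detection-p matrix
#' @param manifest validated probe manifest covering all probes in `bm`
#' @param config a [default_config()] list
#' @return list with `beta` (filtered [beta_matrix()]) and `report`
#'   (a `qc_report`: ordered filter counts, `n_input`, `n_remaining`,
#'   and the detection rule used).
#' @export
apply_probe_filters <- function(bm, manifest, config = default_config()) {
  stopifnot(inherits(bm, "beta_matrix"))
  manifest <- validate_manifest(manifest)
  ids <- rownames(bm$beta)
  missing <- setdiff(ids, manifest$probe_id)
  if (length(missing) > 0)
    stop("probes absent from manifest: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  man <- manifest[match(ids, manifest$probe_id), ]
  nsamp <- ncol(bm$beta)

  fails <- list(
    detection_flawed = if (is.null(bm$detection_p)) rep(FALSE, length(ids))
      else rowSums(bm$detection_p > config$detection_p_cutoff, na.rm = TRUE) > 0,
    snp_adjacent = man$snp_maf > 0.01,
    cross_reactive = man$cross_reactive == 1,
    extreme_beta = rowSums(bm$beta == 0 | bm$beta == 1, na.rm = TRUE) / nsamp >
      config$raw_extreme_frac,
    non_cpg = man$probe_class != "CpG",
    sex_chromosome = man$chrom %in% c("chrX", "chrY", "X", "Y")
  )

  alive <- rep(TRUE, length(ids))
  counts <- integer(length(fails))
  names(counts) <- names(fails)
  for (f in names(fails)) {
    hit <- alive & fails[[f]]
    counts[f] <- sum(hit)
    alive <- alive & !hit
  }

  report <- structure(
    list(filters = data.frame(filter = names(counts),
                              n_removed = unname(counts),
                              stringsAsFactors = FALSE),
         n_input = length(ids), n_remaining = sum(alive),
         detection_rule = sprintf("detection_p > %g in >= 1 sample",
                                  config$detection_p_cutoff)),
    class = "qc_report")
  list(beta = subset_beta(bm, probes = ids[alive]), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("probe QC: %d input -> %d remaining\n", x$n_input, x$n_remaining))
  for (i in seq_len(nrow(x$filters)))
    cat(sprintf("  %-18s %d removed\n",
                x$filters$filter[i], x$filters$n_removed[i]))
  invisible(x)
}
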