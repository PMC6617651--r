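#' Cluster probes by genomic proximity
#'
#' Consecutive probes on the same chromosome join one cluster iff the
#' gap between their positions is strictly less than `max_gap` (a gap
#' of exactly `max_gap` splits).
#'
#' @param manifest validated probe manifest (sorted internally by
#'   chromosome and position)
#' @param max_gap maximum gap in bp (strict), default 500
#' @return integer cluster id named by probe_id, in genomic order
#' @export
cluster_probes <- function(manifest, max_gap = 500L) {
  manifest <- validate_manifest(manifest)
  if (anyDuplicated(manifest[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in manifest")
  ord <- order(manifest$chrom, manifest$pos)
  man <- manifest[ord, ]
  new_cluster <- c(TRUE, man$chrom[-1] != man$chrom[-nrow(man)] |
                     diff(man$pos) >= max_gap)
  cl <- cumsum(new_cluster)
  names(cl) <- man$probe_id
  cl
}

#' Find candidate differentially methylated regions
#'
#' Candidates are maximal runs of consecutive probes within one cluster
#' whose group coefficients share a sign and exceed `cutoff` in
#' absolute value (strict). Per run, `value` is the mean coefficient
#' and `area` the sum of absolute coefficients (the bumphunter region
#' statistic).
#'
#' @param coefs named per-probe group coefficients (delta-beta scale)
#' @param clusters cluster ids from [cluster_probes()], genomic order
#' @param manifest validated manifest (for chrom/pos of run endpoints)
#' @param cutoff |coefficient| candidate threshold (default 0.10)
#' @return data frame: chrom, start, end, n_probes, value, area,
#'   first_probe, probe ids collapsed in `probes`
#' @export
find_candidate_regions <- function(coefs, clusters, manifest, cutoff = 0.10) {
  manifest <- validate_manifest(manifest)
  ids <- names(clusters)
  x <- coefs[ids]
  pos <- manifest$pos[match(ids, manifest$probe_id)]
  chrom <- manifest$chrom[match(ids, manifest$probe_id)]
  pass <- !is.na(x) & abs(x) > cutoff
  sgn <- sign(x)
  # run breaks: cluster change, sign change, or threshold failure
  grp <- cumsum(c(TRUE, clusters[-1] != clusters[-length(clusters)] |
                    sgn[-1] != sgn[-length(sgn)]))
  grp[!pass] <- NA
  runs <- split(which(pass), grp[pass])
  out <- lapply(runs, function(i) {
    data.frame(chrom = chrom[i[1]], start = pos[i[1]], end = pos[i[length(i)]],
               n_probes = length(i), value = mean(x[i]), area = sum(abs(x[i])),
               first_probe = ids[i[1]],
               probes = paste(ids[i], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      value = numeric(0), area = numeric(0),
                      first_probe = character(0), probes = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap null distribution of candidate-region areas
#'
#' Fits the null model (the design without the group column), then for
#' each iteration resamples the residual vectors across samples with
#' replacement, adds them back to the null fitted values, recomputes
#' group coefficients under the full design, and collects the areas of
#' all candidate regions. The pooled areas form the null distribution.
#'
#' @param beta probes x samples matrix aligned with `clusters` order
#' @param design full design matrix including the `group` column
#' @param clusters cluster ids from [cluster_probes()] (all names must
#'   be rows of `beta`)
#' @param manifest validated manifest
#' @param cutoff candidate |coefficient| threshold
#' @param n_boot bootstrap iterations (default 1000)
#' @param seed RNG seed
#' @return numeric vector of pooled null candidate areas (possibly
#'   empty)
#' @export
bootstrap_null <- function(beta, design, clusters, manifest, cutoff = 0.10,
                           n_boot = 1000L, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  ids <- names(clusters)
  B <- beta[ids, , drop = FALSE]
  null_design <- design[, colnames(design) != "group", drop = FALSE]
  fit0 <- fit_probe_models(B, null_design,
                           coef_name = colnames(null_design)[1])
  resid0 <- fit0$residuals
  fitted0 <- fit0$fitted
  n <- ncol(B)
  set.seed(seed)
  areas <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Bb <- fitted0 + resid0[, idx, drop = FALSE]
    fitb <- fit_probe_models(Bb, design)
    cand <- find_candidate_regions(fitb$b, clusters, manifest, cutoff)
    areas[[b]] <- cand$area
  }
  unlist(areas)
}

#' Call DMRs from candidates against a bootstrap null
#'
#' Pooled-null p-values with add-one smoothing:
#' p = (1 + #\{null areas >= observed area\}) / (1 + #null areas).
#' Retains candidates with p < `p_cut` AND at least `min_len` probes;
#' sorted by area descending.
#'
#' @param candidates data frame from [find_candidate_regions()]
#' @param null_areas pooled null areas from [bootstrap_null()]
#' @param p_cut p-value cutoff (default 0.01, strict)
#' @param min_len minimum probes per DMR (default 4)
#' @return the retained candidates with a `p` column
#' @export
call_dmrs <- function(candidates, null_areas, p_cut = 0.01, min_len = 4L) {
  if (length(null_areas) == 0)
    stop("empty null distribution: run bootstrap_null first")
  p <- vapply(candidates$area, function(a)
    (1 + sum(null_areas >= a)) / (1 + length(null_areas)), numeric(1))
  out <- cbind(candidates, p = p)
  out <- out[out$p < p_cut & out$n_probes >= min_len, , drop = FALSE]
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end DMR detection
#'
#' Clusters probes (gaps < `config$max_gap`), takes group coefficients
#' from the covariate-adjusted fit, forms candidates at
#' |coefficient| > `config$min_abs_delta`, bootstraps the null
#' (`config$n_boot` iterations), and retains DMRs at
#' p < `config$dmr_p` with >= `config$dmr_min_len` CpGs.
#'
#' @param bm a [beta_matrix()] (already QC-filtered)
#' @param manifest validated manifest covering the probes
#' @param sheet sample sheet for the modeled samples
#' @param monocyte estimated monocyte proportions aligned with `sheet`
#' @param config a [default_config()]
#' @return list: `dmrs`, `candidates`, `null_areas`, `clusters`
#' @export
find_dmrs <- function(bm, manifest, sheet, monocyte,
                      config = default_config()) {
  stopifnot(inherits(bm, "beta_matrix"))
  keep <- sheet$group %in% c("case", "control")
  sheet <- sheet[keep, , drop = FALSE]
  monocyte <- monocyte[keep]
  man <- validate_manifest(manifest)
  man <- man[man$probe_id %in% rownames(bm$beta), , drop = FALSE]
  clusters <- cluster_probes(man, config$max_gap)
  design <- build_design(sheet, monocyte)
  B <- bm$beta[names(clusters), sheet$sample_id, drop = FALSE]
  fit <- fit_probe_models(B, design)
  cand <- find_candidate_regions(fit$b, clusters, man,
                                 cutoff = config$min_abs_delta)
  if (nrow(cand) == 0)
    return(list(dmrs = cand, candidates = cand, null_areas = numeric(0),
                clusters = clusters))
  null_areas <- bootstrap_null(B, design, clusters, man,
                               cutoff = config$min_abs_delta,
                               n_boot = config$n_boot, seed = config$seed)
  if (length(null_areas) == 0) {
    # a clean null: every observed candidate is more extreme than all
    # (zero) null areas; add-one smoothing still applies
    dmrs <- cbind(cand, p = 1 / (1 + 0))
    dmrs <- dmrs[dmrs$n_probes >= config$dmr_min_len & dmrs$p < config$dmr_p, ,
                 drop = FALSE]
    return(list(dmrs = dmrs, candidates = cand, null_areas = null_areas,
                clusters = clusters))
  }
  dmrs <- call_dmrs(cand, null_areas, p_cut = config$dmr_p,
                    min_len = config$dmr_min_len)
  list(dmrs = dmrs, candidates = cand, null_areas = null_areas,
       clusters = clusters)
}

#' Export DMRs as BED
#'
#' Converts the 1-based, fully-closed probe coordinates to BED's
#' 0-based half-open convention at export.
#'
#' @param dmrs data frame from [call_dmrs()]
#' @param path output BED path
#' @return invisibly, `path`
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end, name = sprintf("DMR%d", seq_len(nrow(dmrs))),
                    score = round(1000 * pmin(1, dmrs$area)),
                    strand = ifelse(dmrs$value > 0, "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
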