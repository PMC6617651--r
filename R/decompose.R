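#' Four-way range-overlap partition of a query sample
#'
#' Classifies each signature CpG of a query sample by where its beta
#' value falls relative to the derivation groups' observed beta ranges
#' (closed intervals, endpoints included):
#' \itemize{
#'   \item `case_typical` — within the case range and outside the
#'     control range;
#'   \item `control_typical` — within the control range and outside the
#'     case range;
#'   \item `both` — within both ranges;
#'   \item `neither` — within neither.
#' }
#' This is the decomposition used to characterize partial (mosaic)
#' signatures. Probes with missing beta are categorized `missing` and
#' excluded from fraction denominators.
#'
#' @param sample_beta named beta vector covering the signature probes
#' @param model a `signature_model` carrying per-group ranges
#' @return a `partition_result`: per-probe data frame (`probe_id`,
#'   `beta`, `category`), summary `counts` and `fractions` over the
#'   four categories, `n_missing`.
#' @export
partition_sites <- function(sample_beta, model) {
  stopifnot(inherits(model, "signature_model"))
  y <- sample_beta[model$probes]
  in_case <- y >= model$case_range[1, ] & y <= model$case_range[2, ]
  in_ctrl <- y >= model$control_range[1, ] & y <= model$control_range[2, ]
  cat <- ifelse(is.na(y), "missing",
         ifelse(in_case & !in_ctrl, "case_typical",
         ifelse(!in_case & in_ctrl, "control_typical",
         ifelse(in_case & in_ctrl, "both", "neither"))))
  levels <- c("case_typical", "control_typical", "neither", "both")
  counts <- vapply(levels, function(l) sum(cat == l, na.rm = TRUE), integer(1))
  n_obs <- sum(counts)
  structure(list(
    probes = data.frame(probe_id = model$probes, beta = unname(y),
                        category = unname(cat), stringsAsFactors = FALSE),
    counts = counts,
    fractions = if (n_obs > 0) counts / n_obs else counts * NA_real_,
    n_missing = sum(cat == "missing")),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("partition over %d signature CpGs (%d missing):\n",
              n + x$n_missing, x$n_missing))
  for (l in names(x$counts))
    cat(sprintf("  %-16s %4d (%5.1f%%)\n", l, x$counts[l],
                100 * x$fractions[l]))
  invisible(x)
}

#' Summarize a partition: percentages, hyper/hypo split, gene majority
#'
#' Per category: counts, percentage of observed probes, and the split
#' into hyper- vs hypo-methylated probes relative to the control median
#' profile (hyper = sample beta above the control profile). With a
#' manifest, the per-gene majority category over each gene's signature
#' probes is also returned (probes annotated to several genes count
#' once per gene).
#'
#' @param partition a `partition_result` from [partition_sites()]
#' @param model the `signature_model` the partition was computed from
#' @param manifest optional validated manifest supplying `genes`
#'   annotations
#' @return list: `table` (category, n, pct, n_hyper, n_hypo),
#'   `gene_majority` (gene, majority_category, n_probes; NULL without a
#'   manifest)
#' @export
summarize_partition <- function(partition, model, manifest = NULL) {
  stopifnot(inherits(partition, "partition_result"),
            inherits(model, "signature_model"))
  pr <- partition$probes
  obs <- pr$category != "missing"
  hyper <- pr$beta > model$control_profile[pr$probe_id]
  n_obs <- sum(obs)
  levels <- names(partition$counts)
  tab <- do.call(rbind, lapply(levels, function(l) {
    sel <- obs & pr$category == l
    data.frame(category = l, n = sum(sel),
               pct = if (n_obs > 0) 100 * sum(sel) / n_obs else NA_real_,
               n_hyper = sum(sel & hyper, na.rm = TRUE),
               n_hypo = sum(sel & !hyper, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  gene_majority <- NULL
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    g <- manifest$genes[match(pr$probe_id, manifest$probe_id)]
    rows <- which(obs & !is.na(g) & g != "")
    if (length(rows) > 0) {
      long <- do.call(rbind, lapply(rows, function(i) {
        syms <- unique(vapply(strsplit(strsplit(g[i], ";")[[1]], ":"),
                              `[`, character(1), 1))
        data.frame(gene = syms, category = pr$category[i],
                   stringsAsFactors = FALSE)
      }))
      gene_majority <- do.call(rbind, lapply(split(long, long$gene),
        function(df) {
          tt <- sort(table(df$category), decreasing = TRUE)
          data.frame(gene = df$gene[1], majority_category = names(tt)[1],
                     n_probes = nrow(df), stringsAsFactors = FALSE)
        }))
      rownames(gene_majority) <- NULL
    }
  }
  list(table = tab, gene_majority = gene_majority)
}
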