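#' Map probes to gene symbols via the manifest
#'
#' Splits the manifest's `genes` annotation ("SYM:region;SYM2:region")
#' and returns the deduplicated gene symbols the probes map to.
#'
#' @param probes probe ids
#' @param manifest validated manifest
#' @return character vector of unique gene symbols
#' @export
probes_to_genes <- function(probes, manifest) {
  manifest <- validate_manifest(manifest)
  g <- manifest$genes[match(probes, manifest$probe_id)]
  g <- g[!is.na(g) & g != ""]
  if (length(g) == 0) return(character(0))
  syms <- unlist(lapply(strsplit(g, ";"), function(parts)
    vapply(strsplit(parts, ":"), `[`, character(1), 1)))
  unique(syms)
}

#' Foreground/background hypergeometric gene-set enrichment
#'
#' Probes are mapped to genes (deduplicated); for each gene set the
#' upper-tail hypergeometric p-value of observing at least the seen
#' number of foreground genes is computed against the background gene
#' universe. Only sets with at least `min_hits` foreground genes are
#' reported; BH adjustment is applied across the reported terms (raw p
#' is kept alongside).
#'
#' @param foreground_probes signature (foreground) probe ids; must be
#'   a subset of the background
#' @param background_probes background probe ids (e.g., all probes
#'   surviving QC)
#' @param manifest validated manifest with gene annotations
#' @param gene_sets named list of gene-symbol vectors (e.g., from
#'   [read_gmt()])
#' @param min_hits minimum foreground genes per reported term
#'   (default 2)
#' @return data frame: set_name, n_hits, n_set, n_foreground,
#'   n_background, fold, p, p_adj — sorted by p
#' @export
hypergeom_enrich <- function(foreground_probes, background_probes,
                             manifest, gene_sets, min_hits = 2L) {
  extra <- setdiff(foreground_probes, background_probes)
  if (length(extra) > 0)
    stop("foreground probes absent from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (length(gene_sets) == 0) stop("no gene sets supplied")
  bg <- probes_to_genes(background_probes, manifest)
  fg <- probes_to_genes(foreground_probes, manifest)
  N <- length(bg); K <- length(fg)
  if (N == 0 || K == 0) stop("no genes mapped from probes")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], bg)
    hits <- length(intersect(fg, set))
    n_set <- length(set)
    p <- stats::phyper(hits - 1, n_set, N - n_set, K, lower.tail = FALSE)
    fold <- if (n_set > 0) (hits / K) / (n_set / N) else 0
    data.frame(set_name = nm, n_hits = hits, n_set = n_set,
               n_foreground = K, n_background = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_hits >= min_hits, , drop = FALSE]
  if (nrow(out) > 0) {
    out$p_adj <- adjust_bh(out$p)
    out <- out[order(out$p, out$set_name), , drop = FALSE]
  } else {
    out$p_adj <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, no continuity correction, upper-tail p —
#' the overlap test used to compare gene lists (e.g., signature genes
#' vs a curated disease gene list).
#'
#' @param a,b,c,d nonnegative cell counts (row-wise: a b / c d)
#' @return list: `chi2`, `p`
#' @export
chisq_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in 2x2 table")
  tt <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(tt$statistic), p = tt$p.value)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then gene
#' symbols, tab-separated. Uses fgsea's parser when available.
#'
#' @param path GMT file path
#' @return named list of gene-symbol vectors
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}
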