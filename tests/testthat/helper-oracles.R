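# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force O(m^2) Benjamini-Hochberg step-up: for the k-th smallest
# p, the adjusted value is min over j >= k of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    best <- 1
    for (j in k:m) best <- min(best, m * ps[j] / j)
    adj[k] <- best
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Sort-based median (midpoint for even n), independent of stats::median.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Tiny manifest builder for filter / clustering fixtures.
tiny_manifest <- function(probe_id, chrom = "chr1", pos = NULL,
                          probe_class = "CpG", snp_maf = 0,
                          cross_reactive = 0L, genes = "") {
  n <- length(probe_id)
  data.frame(probe_id = probe_id,
             chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) seq(1000L, by = 10000L, length.out = n)
                   else pos,
             probe_class = rep_len(probe_class, n),
             snp_maf = rep_len(snp_maf, n),
             cross_reactive = rep_len(cross_reactive, n),
             genes = rep_len(genes, n),
             stringsAsFactors = FALSE)
}

# beta_matrix from a plain matrix with auto ids
bm_fixture <- function(m, probe_ids = NULL, sample_ids = NULL,
                       detection_p = NULL) {
  rownames(m) <- if (is.null(probe_ids)) sprintf("cg%04d", seq_len(nrow(m)))
                 else probe_ids
  colnames(m) <- if (is.null(sample_ids)) sprintf("s%02d", seq_len(ncol(m)))
                 else sample_ids
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(m)
  beta_matrix(m, detection_p)
}

# small simulation used by several files (kept modest for speed)
small_sim <- function(seed = 1, ...) {
  generate_dataset(sim_params(n_probes = 2500, n_signature = 60,
                              n_dmrs = 2, dmr_len = 6, seed = seed, ...))
}

# monocyte column helper
mono_of <- function(props, sheet) props$Mono[match(sheet$sample_id, props$sample_id)]
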