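#' Simulation parameters for a synthetic case-control methylation study
#'
#' Defaults reproduce the statistical structure the analysis assumes:
#' 8 cases vs 23 controls on a 20,000-probe array slice; 300 signature
#' CpGs planted at |delta beta| = 0.15 (half hyper-, half
#' hypo-methylated in cases); measurement noise on the logit scale
#' (sd 0.03); six blood cell types mixed per sample from Dirichlet
#' proportions, with the case concentration vector shifting mass toward
#' monocytes (+0.08 in mean) and away from CD4+ T cells; 50 marker
#' probes per cell type; three planted DMRs of six probes each (spaced
#' 100 bp, members of the signature set); and probe-level artifacts at
#' realistic rates (SNP-adjacent, cross-reactive, detection failures,
#' non-CpG, sex-chromosome probes).
#'
#' @param n_probes total probes on the simulated array
#' @param n_cases,n_controls group sizes
#' @param n_signature planted signature size (includes DMR members)
#' @param effect_delta planted |delta beta| at signature probes, in (0,1)
#' @param hyper_fraction fraction of planted effects that increase beta
#' @param noise_sd measurement noise sd on the logit scale
#' @param n_celltypes number of blood cell types (6 = CD4T, CD8T, Bcell,
#'   NK, Mono, Gran)
#' @param dirichlet_case,dirichlet_control Dirichlet concentration
#'   vectors over cell types (length `n_celltypes`)
#' @param n_discriminating marker probes per cell type
#' @param n_dmrs,dmr_len planted DMR count and length (`dmr_len >= 4`)
#' @param var_probe_frac fraction of probes with extra inter-individual
#'   biological variability (polymorphic/metastable CpGs); these
#'   produce the null candidate regions the DMR bootstrap p-value is
#'   calibrated against
#' @param var_probe_sd logit-scale sd of that biological variability
#' @param artifact_rates named list of per-class probe artifact rates:
#'   `snp`, `cross_reactive`, `detection`, `non_cpg`, `sex_chrom`
#' @param age_range sample age range in years
#' @param seed RNG seed
#' @return a `sim_params` list
#' @export
sim_params <- function(n_probes = 20000L, n_cases = 8L, n_controls = 23L,
                       n_signature = 300L, effect_delta = 0.15,
                       hyper_fraction = 0.5, noise_sd = 0.03,
                       n_celltypes = 6L,
                       dirichlet_case = NULL, dirichlet_control = NULL,
                       n_discriminating = 50L,
                       n_dmrs = 3L, dmr_len = 6L,
                       var_probe_frac = 0.02, var_probe_sd = 0.6,
                       artifact_rates = list(snp = 0.02, cross_reactive = 0.02,
                                             detection = 0.001, non_cpg = 0.002,
                                             sex_chrom = 0.02),
                       age_range = c(3, 25), seed = 1L) {
  celltypes <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Gran")
  if (n_celltypes <= length(celltypes)) {
    celltypes <- celltypes[seq_len(n_celltypes)]
  } else {
    celltypes <- c(celltypes, paste0("CT", seq_len(n_celltypes - length(celltypes))))
  }
  if (is.null(dirichlet_control)) {
    base <- c(CD4T = 0.15, CD8T = 0.08, Bcell = 0.05, NK = 0.04,
              Mono = 0.08, Gran = 0.60)
    m <- if (n_celltypes == 6) base else {
      v <- rep(1 / n_celltypes, n_celltypes); names(v) <- celltypes; v
    }
    dirichlet_control <- m / sum(m) * 150
  }
  if (is.null(dirichlet_case)) {
    m <- dirichlet_control / sum(dirichlet_control)
    # cases: monocytes up, CD4+ T down, in mean
    if ("Mono" %in% celltypes && "CD4T" %in% celltypes) {
      shift <- min(0.08, m[["CD4T"]] * 0.9)
      m[["Mono"]] <- m[["Mono"]] + shift
      m[["CD4T"]] <- m[["CD4T"]] - shift
    }
    dirichlet_case <- m / sum(m) * 150
  }
  p <- list(n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            n_signature = as.integer(n_signature),
            effect_delta = effect_delta, hyper_fraction = hyper_fraction,
            noise_sd = noise_sd, n_celltypes = as.integer(n_celltypes),
            celltypes = celltypes,
            dirichlet_case = unname(dirichlet_case),
            dirichlet_control = unname(dirichlet_control),
            n_discriminating = as.integer(n_discriminating),
            n_dmrs = as.integer(n_dmrs), dmr_len = as.integer(dmr_len),
            var_probe_frac = var_probe_frac, var_probe_sd = var_probe_sd,
            artifact_rates = artifact_rates,
            age_range = age_range, seed = as.integer(seed))
  if (p$n_signature > p$n_probes)
    stop("infeasible layout: n_signature > n_probes")
  if (p$n_dmrs * p$dmr_len > p$n_probes)
    stop("infeasible layout: n_dmrs * dmr_len > n_probes")
  if (p$n_dmrs * p$dmr_len > p$n_signature)
    stop("infeasible layout: planted DMR probes exceed n_signature")
  if (p$n_dmrs > 0 && p$dmr_len < 4)
    stop("dmr_len must be >= 4")
  if (p$effect_delta < 0 || p$effect_delta >= 1)
    stop("effect_delta must lie in [0, 1)")
  if (any(p$dirichlet_case <= 0) || any(p$dirichlet_control <= 0))
    stop("Dirichlet concentrations must be positive")
  if (length(p$dirichlet_case) != p$n_celltypes ||
      length(p$dirichlet_control) != p$n_celltypes)
    stop("Dirichlet concentration length must equal n_celltypes")
  structure(p, class = "sim_params")
}

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Deterministic probe layout + cell-type profiles for a parameter set.
# Re-seeds from params$seed so generate_reference_panel() reproduces the
# exact profiles generate_dataset() mixes from.
sim_structure <- function(params) {
  set.seed(params$seed)
  n <- params$n_probes
  K <- params$n_celltypes
  rates <- params$artifact_rates
  n_sex <- round(rates$sex_chrom * n)
  n_auto <- n - n_sex
  if (n_auto < params$n_signature + 10)
    stop("infeasible layout: too few autosomal probes")

  # contiguous autosomal blocks over chr1..chr22, default inter-probe
  # gap 2000 bp (every probe its own DMR cluster unless in a planted run)
  n_chr <- min(22L, n_auto)
  sizes <- diff(round(seq(0, n_auto, length.out = n_chr + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chr)), sizes)
  gap <- rep(2000L, n_auto)

  # planted DMR runs: dmr_len consecutive slots at 100 bp spacing
  dmr_slot <- integer(0)
  dmr_id <- integer(0)
  next_free <- cumsum(c(1, sizes[-n_chr]))  # first slot index per chrom
  chrom_end <- cumsum(sizes)
  run_cursor <- next_free + 2L
  if (params$n_dmrs > 0) {
    for (d in seq_len(params$n_dmrs)) {
      cd <- ((d - 1L) %% n_chr) + 1L
      start <- run_cursor[cd]
      if (start + params$dmr_len - 1L > chrom_end[cd])
        stop("infeasible layout: chromosome block too small for planted DMRs")
      slots <- start:(start + params$dmr_len - 1L)
      gap[slots[-1]] <- 100L
      dmr_slot <- c(dmr_slot, slots)
      dmr_id <- c(dmr_id, rep(d, params$dmr_len))
      run_cursor[cd] <- start + params$dmr_len + 4L
    }
  }

  # positions: cumulative gaps within each chromosome, 1-based
  pos <- integer(n_auto)
  for (ci in seq_len(n_chr)) {
    idx <- which(chrom == paste0("chr", ci))
    pos[idx] <- 10000L + cumsum(c(0L, gap[idx[-1]]))
  }

  # scattered signature probes among non-DMR autosomal slots
  n_scatter <- params$n_signature - length(dmr_slot)
  free <- setdiff(seq_len(n_auto), dmr_slot)
  scatter_slot <- sort(sample(free, n_scatter))
  sig_slot <- c(dmr_slot, scatter_slot)
  free <- setdiff(free, scatter_slot)

  take <- function(rate) {
    k <- min(round(rate * n), length(free))
    s <- if (k > 0) sort(sample(free, k)) else integer(0)
    free <<- setdiff(free, s)
    s
  }
  snp_slot <- take(rates$snp)
  xr_slot <- take(rates$cross_reactive)
  det_slot <- take(rates$detection)
  ncpg_slot <- take(rates$non_cpg)

  # cell-type marker probes, disjoint per type, half hyper / half hypo
  marker_slot <- vector("list", K)
  for (k in seq_len(K)) {
    s <- sort(sample(free, params$n_discriminating))
    free <- setdiff(free, s)
    marker_slot[[k]] <- s
  }

  # biologically variable CpGs (disjoint from signature/markers/artifacts):
  # probe-specific inter-individual logit-scale sd
  var_slot <- take(params$var_probe_frac)
  var_sd <- params$var_probe_sd * stats::runif(length(var_slot), 0.5, 1.5)

  # signed effects: DMR runs share one sign, scattered probes independent
  sign_vec <- numeric(params$n_signature)
  if (length(dmr_slot) > 0) {
    dmr_sign <- ifelse(stats::runif(params$n_dmrs) < params$hyper_fraction, 1, -1)
    sign_vec[seq_along(dmr_slot)] <- dmr_sign[dmr_id]
  }
  if (n_scatter > 0) {
    n_hyper <- round(params$hyper_fraction * n_scatter)
    s <- c(rep(1, n_hyper), rep(-1, n_scatter - n_hyper))
    sign_vec[length(dmr_slot) + seq_len(n_scatter)] <- sample(s)
  }

  # baseline beta: bimodal mixture (low ~0.1 / high ~0.85 modes);
  # signature baselines drawn so the planted shift stays inside (0,1)
  m <- ifelse(stats::runif(n_auto) < 0.5,
              stats::rbeta(n_auto, 2, 18), stats::rbeta(n_auto, 17, 3))
  m <- clip01(m, 0.01)
  e <- params$effect_delta
  hyper <- sig_slot[sign_vec > 0]
  hypo <- sig_slot[sign_vec < 0]
  m[hyper] <- stats::runif(length(hyper), 0.15, max(0.16, 0.85 - e))
  m[hypo] <- stats::runif(length(hypo), min(0.84, 0.15 + e), 0.85)

  # profiles: shared baseline except at marker probes
  profiles <- matrix(m, nrow = n_auto, ncol = K)
  colnames(profiles) <- params$celltypes
  for (k in seq_len(K)) {
    s <- marker_slot[[k]]
    h <- s[seq_len(floor(length(s) / 2))]
    l <- setdiff(s, h)
    profiles[h, ] <- 0.10; profiles[h, k] <- 0.90
    profiles[l, ] <- 0.90; profiles[l, k] <- 0.10
  }

  # sex-chromosome probes appended after the autosomes
  if (n_sex > 0) {
    sx <- rep(c("chrX", "chrY"), length.out = n_sex)
    sx <- sx[order(sx)]
    chrom <- c(chrom, sx)
    pos <- c(pos, unlist(lapply(split(seq_len(n_sex), sx), function(i)
      10000L + 2000L * (seq_along(i) - 1L)), use.names = FALSE))
    mx <- ifelse(stats::runif(n_sex) < 0.5,
                 stats::rbeta(n_sex, 2, 18), stats::rbeta(n_sex, 17, 3))
    profiles <- rbind(profiles, matrix(clip01(mx, 0.01), n_sex, K))
  }

  ids <- sprintf("cg%07d", seq_len(n))
  artifact <- rep("none", n)
  artifact[snp_slot] <- "snp"
  artifact[xr_slot] <- "cross_reactive"
  artifact[det_slot] <- "detection"
  artifact[ncpg_slot] <- "non_cpg"
  if (n_sex > 0) artifact[(n_auto + 1):n] <- "sex_chrom"

  # gene annotation: ~1 gene per 3 probes, region label varies
  gene_idx <- ceiling(seq_len(n) / 3)
  region <- sample(c("promoter", "5'UTR", "body"), n, replace = TRUE,
                   prob = c(0.3, 0.1, 0.6))
  genes <- sprintf("G%05d:%s", gene_idx, region)
  genes[stats::runif(n) < 0.15] <- ""  # intergenic probes

  snp_maf <- rep(0, n)
  snp_maf[snp_slot] <- stats::runif(length(snp_slot), 0.02, 0.5)
  probe_class <- rep("CpG", n)
  probe_class[ncpg_slot] <- "non-CpG"

  manifest <- data.frame(probe_id = ids, chrom = chrom, pos = as.integer(pos),
                         probe_class = probe_class, snp_maf = snp_maf,
                         cross_reactive = as.integer(seq_len(n) %in% xr_slot),
                         genes = genes, stringsAsFactors = FALSE)
  rownames(profiles) <- ids

  sig_ids <- ids[sig_slot]
  shift <- numeric(params$n_signature)
  target <- clip01(m[sig_slot] + sign_vec * e, 0.005)
  shift <- stats::qlogis(target) - stats::qlogis(m[sig_slot])

  planted_dmrs <- NULL
  if (params$n_dmrs > 0) {
    planted_dmrs <- do.call(rbind, lapply(seq_len(params$n_dmrs), function(d) {
      s <- dmr_slot[dmr_id == d]
      data.frame(dmr = d, chrom = chrom[s[1]], start = pos[s[1]],
                 end = pos[s[length(s)]], n_probes = length(s),
                 effect = sign_vec[match(s[1], sig_slot)] * e,
                 stringsAsFactors = FALSE)
    }))
  }

  list(manifest = manifest, profiles = profiles,
       signature = data.frame(probe_id = sig_ids,
                              effect = sign_vec * e,
                              logit_shift = shift,
                              stringsAsFactors = FALSE),
       marker_ids = lapply(marker_slot, function(s) ids[s]),
       var_probes = data.frame(probe_id = ids[var_slot], sd = var_sd,
                               stringsAsFactors = FALSE),
       det_ids = ids[det_slot],
       planted_dmrs = planted_dmrs,
       artifact = data.frame(probe_id = ids, artifact = artifact,
                             stringsAsFactors = FALSE))
}

#' Generate a synthetic case-control methylation dataset
#'
#' Bulk beta values are proportion-weighted mixtures of cell-type
#' profiles; the planted case effect and measurement noise are applied
#' on the logit scale and transformed back, so values stay in \[0,1\]
#' without truncation artifacts.
#'
#' @param params a [sim_params()] object
#' @return a list of class `methsig_sim` with elements `beta`
#'   ([beta_matrix()] with detection p-values), `manifest`, `samples`
#'   (sample sheet), and `truth` (planted signature probes with signed
#'   effects, true cell proportions, planted DMRs, per-probe artifact
#'   labels).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  st <- sim_structure(params)  # seeds the RNG from params$seed
  n <- params$n_probes
  ncs <- params$n_cases; nct <- params$n_controls
  ns <- ncs + nct
  ids <- st$manifest$probe_id

  grp <- c(rep("case", ncs), rep("control", nct))
  sam <- sprintf("%s%02d", ifelse(grp == "case", "case", "ctrl"),
                 c(seq_len(ncs), seq_len(nct)))

  W <- rbind(rdirichlet(ncs, params$dirichlet_case),
             rdirichlet(nct, params$dirichlet_control))
  dimnames(W) <- list(sam, params$celltypes)

  bulk <- st$profiles %*% t(W)  # probes x samples

  lg <- stats::qlogis(clip01(bulk))
  sig_row <- match(st$signature$probe_id, ids)
  lg[sig_row, grp == "case"] <- lg[sig_row, grp == "case"] + st$signature$logit_shift
  lg <- lg + matrix(stats::rnorm(n * ns, 0, params$noise_sd), n, ns)
  if (nrow(st$var_probes) > 0) {
    vr <- match(st$var_probes$probe_id, ids)
    lg[vr, ] <- lg[vr, ] +
      matrix(stats::rnorm(length(vr) * ns, 0, st$var_probes$sd),
             length(vr), ns)
  }
  beta <- stats::plogis(lg)
  dimnames(beta) <- list(ids, sam)

  detp <- matrix(stats::runif(n * ns, 0, 1e-4), n, ns, dimnames = dimnames(beta))
  if (length(st$det_ids) > 0) {
    for (pid in st$det_ids) {
      nfail <- 1L + stats::rbinom(1, ns - 1L, 0.1)
      cols <- sample(ns, nfail)
      detp[pid, cols] <- stats::runif(nfail, 0.02, 0.5)
    }
  }

  sheet <- data.frame(sample_id = sam, group = grp,
                      age = round(stats::runif(ns, params$age_range[1],
                                               params$age_range[2]), 1),
                      sex = stats::rbinom(ns, 1, 0.5),
                      replicate_of = NA_character_,
                      stringsAsFactors = FALSE)

  truth <- list(signature = st$signature,
                true_proportions = W,
                planted_dmrs = st$planted_dmrs,
                artifact_labels = st$artifact,
                marker_ids = st$marker_ids,
                variable_probes = st$var_probes)

  structure(list(beta = beta_matrix(beta, detp),
                 manifest = validate_manifest(st$manifest),
                 samples = validate_sample_sheet(sheet),
                 truth = truth,
                 profiles = st$profiles,
                 params = params),
            class = "methsig_sim")
}

#' Generate a mosaic (partial-signature) query sample
#'
#' Emulates a sample whose methylation matches cases at a random subset
#' of signature CpGs and controls elsewhere — the partial-signature
#' pattern seen in intermediate-scoring patients.
#'
#' @param dataset a `methsig_sim` from [generate_dataset()]
#' @param fraction fraction of signature probes carrying the case
#'   effect, in \[0,1\]
#' @param seed RNG seed for the mask and the sample's noise
#' @return list with `beta` (named vector over all probes), `mask`
#'   (logical vector named by signature probe id; TRUE = case effect
#'   present), and `sample_id`.
#' @export
generate_mosaic_sample <- function(dataset, fraction, seed = 1L) {
  stopifnot(inherits(dataset, "methsig_sim"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]")
  params <- dataset$params
  set.seed(seed)
  sig <- dataset$truth$signature
  nsig <- nrow(sig)
  k <- round(fraction * nsig)
  mask <- rep(FALSE, nsig)
  if (k > 0) mask[sample(nsig, k)] <- TRUE
  names(mask) <- sig$probe_id

  w <- rdirichlet(1, params$dirichlet_control)[1, ]
  bulk <- as.vector(dataset$profiles %*% w)
  lg <- stats::qlogis(clip01(bulk))
  rows <- match(sig$probe_id[mask], rownames(dataset$profiles))
  lg[rows] <- lg[rows] + sig$logit_shift[mask]
  lg <- lg + stats::rnorm(length(lg), 0, params$noise_sd)
  vp <- dataset$truth$variable_probes
  if (!is.null(vp) && nrow(vp) > 0) {
    vr <- match(vp$probe_id, rownames(dataset$profiles))
    lg[vr] <- lg[vr] + stats::rnorm(length(vr), 0, vp$sd)
  }
  beta <- stats::plogis(lg)
  names(beta) <- rownames(dataset$profiles)
  list(beta = beta, mask = mask,
       sample_id = sprintf("mosaic_f%03d_s%d", round(100 * fraction), seed))
}

#' Generate a sorted-cell reference panel consistent with a simulation
#'
#' Returns the exact cell-type mean profiles over marker probes that
#' [generate_dataset()] mixes bulk samples from (same `params`, same
#' seed), plus a noisy sorted-cell beta matrix usable to exercise marker
#' selection.
#'
#' @param params a [sim_params()] object
#' @param n_replicates sorted-cell replicate samples per cell type in
#'   the accompanying source matrix
#' @param source_noise_sd logit-scale noise of the source replicates
#' @return list with `panel` (a `celltype_panel`: `cell_types`,
#'   `marker_probes`, `reference` cell types x markers), `source_beta`
#'   (markers x replicate samples), `source_labels`.
#' @export
generate_reference_panel <- function(params, n_replicates = 3L,
                                     source_noise_sd = 0.05) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_discriminating < 1) stop("n_discriminating must be >= 1")
  st <- sim_structure(params)
  marker_ids <- unlist(st$marker_ids)
  ref <- t(st$profiles[marker_ids, , drop = FALSE])  # cell types x markers
  panel <- celltype_panel(cell_types = params$celltypes,
                          marker_probes = marker_ids,
                          reference = ref)
  nrep <- as.integer(n_replicates)
  src <- NULL; labels <- NULL
  if (nrep > 0) {
    K <- params$n_celltypes
    src <- matrix(0, length(marker_ids), K * nrep)
    labels <- rep(params$celltypes, each = nrep)
    cn <- sprintf("%s_rep%d", labels, rep(seq_len(nrep), K))
    for (k in seq_len(K)) {
      mu <- stats::qlogis(clip01(st$profiles[marker_ids, k]))
      for (r in seq_len(nrep)) {
        src[, (k - 1) * nrep + r] <-
          stats::plogis(mu + stats::rnorm(length(mu), 0, source_noise_sd))
      }
    }
    dimnames(src) <- list(marker_ids, cn)
  }
  list(panel = panel, source_beta = src, source_labels = labels)
}
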