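---
title: "Deriving and applying a blood DNA methylation signature"
author: "methsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a blood DNA methylation signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsig)
```

## The problem

Rare neurodevelopmental disorders caused by variants in epigenetic
regulator genes leave reproducible genome-wide traces in blood DNA
methylation — *episignatures*. Once such a signature is derived from a
small case-control cohort, it can classify variants of uncertain
significance (VUS) in the same gene: a patient's methylation profile
either resembles the case reference or it does not, regardless of what
in-silico protein predictions say. `methsig` implements the complete
workflow on Illumina EPIC-style beta values: probe quality control,
blood cell-type deconvolution, covariate-adjusted moderated
differential methylation, signature selection, correlation-based
scoring, partial-signature decomposition, region-level (DMR) analysis,
and gene-set enrichment. A synthetic-data generator reproduces the
statistical structure of such a study so every stage is testable
without microarray downloads.

## The model, stage by stage

### Probe quality control

Arrays carry probes that cannot be interpreted as clean CpG
methylation: probes failing detection, probes whose signal is altered
by a nearby common SNP, cross-reactive probes, probes pinned at beta
exactly 0 or 1, non-CpG probes, and sex-chromosome probes (removed
because cohorts mix sexes). `apply_probe_filters()` removes these in a
fixed order and attributes each probe to the *first* rule it fails, so
the per-filter counts sum to the total removed — the convention that
makes a QC report add up. Reapplying the filters to their own output
removes nothing, and the surviving set does not depend on the rule
order (only the attribution of counts does).

The detection rule is a genuine design decision: public method
descriptions rarely state one. We use *detection p > 0.01 in at least
one sample*, and record the rule inside the QC report so downstream
consumers see exactly what was applied.

### Cell-type deconvolution

Whole blood is a mixture; any disorder that shifts blood composition
shifts bulk methylation at cell-type marker CpGs. Proportions are
estimated per sample by the reference-based (Houseman-style)
projection: minimize \(\lVert y - R^\top c\rVert^2\) subject to
\(c \ge 0\) and \(\sum c \le 1\), where \(R\) holds the sorted-cell
mean profiles over marker probes. The inequality (rather than
\(\sum c = 1\)) leaves room for unmodeled cell types; the unexplained
mass is reported. The quadratic program is solved exactly (via
`quadprog`), so noiseless mixtures are recovered to numerical
precision.

Group comparison of estimated proportions uses the equal-variance
Student t-test. When two cell types shift in opposite, correlated
directions (monocytes up, CD4+ T down in cases), only the more
significant one — the monocyte proportion — enters the regression
model as a covariate; including both would be near-collinear.

### Differential methylation and signature selection

Each probe's beta values are regressed on group, age, sex, and
monocyte proportion. With 31 samples, per-probe variance estimates are
noisy, so they are moderated by empirical Bayes: the prior
\(s^2 \sim s_0^2 F(d, d_0)\) is fit by matching the first two moments
of \(\log s^2\) (the prior degrees of freedom solve a trigamma
equation, inverted by Newton's method), and each probe's variance
shrinks to \(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\), with the
moderated t on \(d_0 + d\) degrees of freedom. Two limits are exact by
construction: if the spread of \(\log s^2\) is no larger than sampling
noise, \(d_0 = \infty\) and every \(\tilde s^2\) equals the pooled
mean variance; injecting \(d_0 = 0\) recovers the ordinary t. The
implementation is cross-checked against limma's independent
implementation in the unit tests.

Signature CpGs must pass **both** a Benjamini-Hochberg adjusted
p-value strictly below 0.05 and an absolute group difference in mean
beta strictly above 0.10. The effect-size filter is deliberately on
the *raw* beta scale (not the adjusted coefficient): "10% methylation
difference" is a raw-scale statement, and the dual criterion is what
keeps composition-driven or barely-significant probes out of the
signature. Signature derivation uses only case/control samples older
than `min_age` years (default 2; age has a strong effect on DNAm in
infancy). Probes are ordered by adjusted p, then |delta beta|
descending, then probe id — a full, reproducible tie-break.

Two-sided p-values are used throughout: both hyper- and
hypo-methylated CpGs belong in a signature.

### Scoring and classification

The signature model stores, per signature CpG, the median beta across
derivation cases and across derivation controls (midpoint median for
even group sizes), plus each group's observed [min, max] range. A
query sample's score is

\[
\mathrm{score} = r(B_\mathrm{sig},\ \text{case profile}) -
                 r(B_\mathrm{sig},\ \text{control profile}),
\]

the difference of Pearson correlations between the sample's
signature-site beta vector and the two profiles. Positive scores
classify as "pathogenic", negative as "benign". Pearson correlation
makes the score invariant to affine shifts of the sample vector (so
global intensity effects cancel) and antisymmetric under swapping the
profiles. A score of exactly 0 is labeled "benign" with a warning —
the boundary case has no principled side. Samples missing more than
10% of signature probes are refused rather than scored on a sliver;
below that, pairwise-complete correlation is used.

### Partial (mosaic) signatures

Some patients match cases at one subset of signature CpGs and controls
at another — an intermediate score with a biologically meaningful
structure. `partition_sites()` classifies each signature CpG of a
query sample into four exhaustive categories by where its beta falls
relative to the derivation groups' observed ranges: case-typical
(inside the case range, outside the control range), control-typical
(the reverse), both, or neither. Ranges are closed intervals with
endpoints included: "within the observed range" reads inclusively.
The summary adds a hyper/hypo split relative to the control profile
and a per-gene majority category, since partial signatures tend to be
coherent within genes.

The case-typical *fraction* systematically underestimates the true
mosaic fraction by a few percentage points: a case-level value can
still fall inside the control min–max range (23 controls produce wide
ranges), landing in "both". This bias is visible in the synthetic
recovery test and is inherent to the range-overlap definition, which
is intentionally conservative.

### DMR detection

Regions are built from probes clustered at inter-probe gaps strictly
below 500 bp; candidates are maximal same-sign runs of probes whose
adjusted group coefficient exceeds 0.10 in absolute value. The region
statistic is the *area* — the sum of absolute coefficients — the
default statistic of the bumphunter family. Significance comes from a
bootstrap under the null model: fit the design without the group
column, resample residual vectors across samples with replacement, add
them back to the null fits, recompute coefficients and candidate
areas, and pool all null areas over the iterations. The p-value uses
add-one smoothing, \(p = (1 + \#\{A_\mathrm{null} \ge A\})/(1 +
N_\mathrm{null})\), which never returns exactly zero. Reported DMRs
need p < 0.01 and at least 4 CpGs. No coefficient smoothing across
probes is applied; the minimum run length already enforces spatial
support, and smoothing parameters would be one more unconstrained
choice.

### Enrichment

Signature probes are mapped to genes through the manifest annotation
(deduplicated; multi-gene probes count once per gene), and each gene
set is tested with the upper-tail hypergeometric against the
background of genes mapped from all QC-surviving probes — the
foreground/background design of region-based GO tools. Terms need at
least two foreground genes to be reported; BH adjustment is applied
across reported terms (with raw p kept, since the multiplicity
handling of the original analysis is unstated). The 2×2 overlap test
against a curated gene list is the Pearson chi-square with one degree
of freedom and no continuity correction.

## What the generator emulates — and what it does not

`generate_dataset()` produces the statistical structure the analysis
assumes, with defaults fixed at the study conditions:

* **Cohort**: 8 cases vs 23 controls, ages uniform on 3–25 years,
  random sex.
* **Baseline methylation**: a bimodal mixture with modes near beta 0.1
  and 0.85, matching genome-wide beta distributions.
* **Cell-type mixing**: six blood cell types (CD4T, CD8T, B, NK,
  monocytes, granulocytes) with per-sample Dirichlet proportions
  (granulocyte-dominant, total concentration 150 so proportion sds are
  a realistic ~2%); the case concentration vector moves 0.08 of mean
  mass from CD4+ T to monocytes. Each cell type has 50 marker probes
  (half hyper-, half hypomethylated in that type); bulk beta is the
  proportion-weighted mixture of cell-type profiles.
* **Signature**: 300 CpGs at |delta beta| = 0.15, half hyper/half
  hypo. Effects are applied on the logit scale and transformed back,
  so beta stays in [0,1] without truncation spikes; the logit shift is
  calibrated so the *beta-scale* group difference equals the nominal
  effect.
* **Noise**: measurement noise on the logit scale (sd 0.03), plus a 2%
  class of biologically variable CpGs (probe-specific logit sd around
  0.6, disjoint from signature and marker probes). These variable CpGs
  emulate polymorphic/metastable loci; they are what populates the
  bootstrap null with candidate areas — without them a synthetic null
  has no bumps at all and the pooled bootstrap p-value degenerates.
* **Structure for DMRs**: three signature regions of six probes at
  100 bp spacing (one sign per region); all other probes sit 2,000 bp
  apart, so they form singleton clusters.
* **Artifacts**: SNP-adjacent (2%), cross-reactive (2%), detection
  failures (0.1%), non-CpG (0.2%), and sex-chromosome probes (2%),
  each flagged in the manifest and labeled in the ground truth.
* **Mosaic samples**: `generate_mosaic_sample()` draws a control-like
  sample that carries the case effect at a uniformly random fraction
  of signature CpGs, with the mask recorded. (Gene-coherent masks are
  a documented option of the real phenomenon but the default mask is
  uniform, which is the harder case for the partition to recover.)

Not emulated: Infinium I/II probe-chemistry differences, chip/batch
effects, age- or sex-dependent methylation trends, genomic
autocorrelation beyond the planted regions, and realistic linkage
between SNP artifacts and beta distributions. Consequently, passing
tests demonstrate that the *algorithms* recover what was planted under
the stated noise model; they do not demonstrate robustness to
normalization artifacts or batch structure in real cohorts, which must
be handled upstream.

## Numerical choices and degenerate inputs

* Beta values are clipped to [1e-6, 1 − 1e-6] before logit transforms.
* `estimate_proportions()` adds a 1e-10 ridge to the normal equations
  so collinear reference profiles do not crash the QP; exact mixtures
  are still recovered to 1e-6 and better.
* Marker selection keeps infinite t-statistics (perfect separation at
  zero within-type variance) at the top of the ranking; 0/0 becomes 0,
  and fully indistinguishable cell types trigger a warning.
* All-zero residual variances abort moderation (a degenerate fit);
  single zero variances shrink to the prior.
* An empty signature is legal output of selection (flagged with a
  warning); scoring refuses it, and the pipeline reports the failure
  at the scoring stage with partial results attached.
* Bootstrap determinism: the DMR null is seeded from the pipeline
  config, so identical seeds reproduce result tables byte for byte.

## Design decisions where the method description was open

* **min_age defaults to 2 years.** The derivation description says
  samples older than 2 were used; a later section says greater than 3.
  The parameter is exposed; 2 is the default.
* **Sequential QC attribution.** Whether published per-filter counts
  were sequential or independent is not derivable from six totals;
  sequential is the convention that makes counts sum.
* **Leave-one-out profiles are not used**: derivation samples are
  scored against the fixed profiles they helped build. This inflates
  their scores slightly but matches the published classification
  design, where validation used independent cohorts.
* **Complete linkage** for the sample dendrogram (the distance metric,
  Euclidean, is stated; the linkage is not). Configurable.
* **Scores are reported to full precision** and compared at 2 decimals
  where a printed table is the reference.

## Problem sizes used by the tests

The packaged test suite and the acceptance script run the full
workflow at 20,000 probes (the signature-recovery study), with
auxiliary studies of 2,000–4,000 probes for calibration replicates,
deconvolution accuracy, and DMR detection (200 bootstrap iterations),
and 50,000 simulated variances for the moderation-recovery check.
These sizes give stable Monte-Carlo behaviour while keeping a complete
run in well under a minute; the analysis scripts under `analysis/` use
the same 20,000-probe study with the full 1,000 bootstrap iterations.

## Known limitations

* The score's decision threshold is fixed at 0; no probabilistic
  calibration or confidence band is attached to a classification.
* The partition is descriptive: no test against a null mosaic fraction
  is performed.
* Gene mapping comes from the manifest only; regulatory-domain
  (GREAT-style) region-to-gene assignment is out of scope, so
  enrichment results depend on the annotation supplied.
* Reference panels are inputs: the package does not re-derive a
  sorted-cell reference from raw data.
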