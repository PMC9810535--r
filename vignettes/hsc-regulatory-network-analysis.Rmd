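---
title: "Deriving and testing an HSC regulatory network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and testing an HSC regulatory network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemenet)
```

## Scope and overview

`hemenet` implements the computational chain used to characterize a
transcription-factor-centered regulatory network that maintains
hematopoietic stem cells (HSCs), and to ask whether that network carries
prognostic information in acute myeloid leukemia (AML). The chain has six
analysis stages, each usable on its own:

1. **Network discovery** — two-condition single-cell differential
   expression with a two-part hurdle test, validated by a label-permutation
   null and by pseudobulk concordance; per-cell marker-signature scoring.
2. **Lineage enrichment** — a permutation z-score for the mean expression
   of a gene set across hematopoietic cell types.
3. **cisRE–gene linking** — a catalog of cis-regulatory elements (cisREs)
   merged across populations, accessibility–expression correlation within
   a TSS window, an empirical trans-pair null, and selection of the
   HSC-open, significant links into a network.
4. **Footprint statistics** — aggregate Tn5 cleavage profiles, pairwise
   co-occurrence by a two-sided hypergeometric test, occupancy enrichment
   by genome permutation, footprint spacing, and paired cross-lineage
   signal contrasts.
5. **Chromatin loops** — Knight–Ruiz balancing of contact maps, aggregate
   peak analysis (APA) with the peak-to-lower-left ratio (P2LL), loop
   classification by CTCF anchors and network cisREs, and corner-background
   contrasts.
6. **Survival stratification** — per-sample preranked GSEA against the
   network gene set, Youden-threshold dichotomization, Kaplan–Meier /
   log-rank / trend testing, Cox models with Efron ties, marginal hazard
   curves, and expression-stratified CRISPR-essentiality contrasts.

A seventh, first-class module generates every input the pipeline consumes,
with planted ground truth, so all stages are testable without external
downloads.

## Coordinate and data conventions

All genomic intervals are 0-based, half-open (BED dialect), including
BEDPE loop anchors; intervals sharing only an endpoint do not overlap.
Count matrices are cells x genes; profile and multiomic matrices are
features x populations. Contact maps are per-chromosome symmetric matrices
at fixed resolution (default 25 kb).

## The hurdle differential-expression test

Single-cell perturbation data are sparse and zero-inflated; the package
tests each gene with a two-part likelihood-ratio statistic:

* a Bernoulli component on the detection indicator (expressed / not), and
* a Gaussian component on the log-normalized nonzero values, with a
  variance shared between groups.

The two log-likelihood-ratio parts add and are referred to a chi-square
with 2 degrees of freedom; when a gene is detected in only one group the
continuous component is undefined and the statistic drops to 1 df. This is
the hurdle principle popularized by MAST, deliberately without MAST's
cellular-detection-rate covariate: the test is a clean two-sample hurdle
LRT whose null behavior we can verify directly (label-permutation p-values
are uniform/super-uniform in the test suite). Exact reproduction of a
Seurat+MAST gene list would require matching that tool's covariates and
options; the package documents this divergence rather than emulating it.

Normalization is `log2(1 + count / libsize * 1e4)` (log2 of CPM/100),
and the reported `log2fc` is the difference of group means of those
values, oriented reference (control) minus perturbed, so "down" network
genes — genes that lose expression after perturbation — have positive
`log2fc`. Network calls use the discovery thresholds `log2fc > 0.05` and
Bonferroni-adjusted `p < 1e-20`; the detection filter (gene tested when
detected in at least 5% of either group's cells) is configurable because
published descriptions of such filters are often ambiguous between the
integration and testing steps.

Two independent validations mirror the original analysis design:

* **Permutation null**: labels are shuffled (100 permutations by default)
  and the network-calling thresholds applied; on exchangeable data this
  yields zero called genes in every permutation.
* **Pseudobulk concordance**: raw counts are summed per condition,
  CPM-log transformed, and the pseudobulk log2 fold change is compared to
  the single-cell fold change by Spearman correlation with a
  label-permutation p-value. Genes that fail the single-cell detection
  cutoff are excluded, matching the discovery step.

The per-cell signature score (default HSC trio CD34/HLF/CRHBP) min–max
scales each signature gene across cells before averaging, so the
conventional 0.5 cutoff is meaningful regardless of expression scale. The
published plots do not state their exact scaling; min–max is our explicit
stand-in and is flagged as such.

## Lineage permutation z-scores

For a gene set and a genes x cell-types profile matrix, the observed
statistic per cell type is the mean expression of the set; `n_perm`
same-size gene sets are drawn uniformly from all matrix genes and

\[ z_{j} = \frac{y_{j} - \mathrm{mean}(y^{(P)}_{j})}{\mathrm{s.d.}(y^{(P)}_{j})} \]

with moments taken per cell type over the permutation draws (one permuted
set is scored on all cell types, so columns share draws). When
`choose(n_genes, |set|) <= 10000` the implementation enumerates all
subsets, making the z exact; the test suite checks exhaustive mode against
an independent enumeration oracle to machine precision. The permutation
universe is all genes in the matrix — the published formula does not state
a universe — and an optional flag matches permuted genes on
mean-expression decile for sensitivity analysis. A degenerate permutation
s.d. of zero (e.g. constant matrices) reports z = 0 with a warning rather
than NaN.

## cisRE–gene linking

The cisRE catalog is the merged union of per-population accessibility
peaks, each element annotated with the populations whose peaks overlap it.
Links are scored for all (cisRE, gene) pairs whose cisRE midpoint falls
within 500 kb of the gene's TSS: the statistic is the Pearson correlation
of accessibility and expression across the shared population axis. The
null is built from trans pairs (random cisRE x gene on different
chromosomes), giving a one-sided empirical p for positive association,
`(1 + #{r_null >= r}) / (n_perm + 1)`, with Benjamini–Hochberg adjustment.
The HSC-specific network keeps links with `q < 0.05` and positive HSC
accessibility, weighting each by `r * minmax(HSC accessibility)`.

The original framework's internals are described in a supplementary note
that is not part of the available text; this scoring — distance-windowed
correlation, trans-pair empirical null, HSC-accessibility weighting — is a
principled reconstruction of the stated ingredients, and every constant
(window, q threshold, weighting) is exposed as an argument. It should be
read as this package's own operationalization, not as a replica.

Motif similarity between two position frequency matrices normalizes
columns to frequencies and maximizes the Pearson correlation of flattened
overlapping columns over all offsets with at least 5 overlapping columns,
in both orientations (reverse complement included, since biologically the
matched motifs can be reported on either strand). Significance comes from
column-shuffling the second motif. Degenerate (zero-variance) windows are
skipped; if every window is degenerate — e.g. a uniform matrix — the
comparison errors rather than reporting an undefined correlation.

## Footprint statistics

* **Cleavage profiles** sum per-base cut counts across same-width motif
  sites (minus-strand windows reversed) and normalize to probabilities.
* **Co-occurrence** treats each TF's membership as the set of cisREs
  containing at least one of its footprints and tests each pair with a
  two-sided hypergeometric p defined by summing point masses no larger
  than the observed one (the "method of small p-values"); that definition
  is exactly testable by enumeration, which the suite does for N = 12.
* **Occupancy enrichment** counts cisREs overlapping at least one TF peak
  and compares against 1,000 re-placements of an equal number of
  same-length peaks, chromosomes drawn proportional to length and starts
  uniform. Whether the original analysis constrained permuted peaks to
  mappable regions is unstated; the uniform-genome choice is ours, and
  placed peaks may overlap each other since only count equality is stated.
  The empirical p has floor `1/(n_perm + 1)`.
* **Spacing** between two TFs within a cisRE is the minimal edge-to-edge
  gap over footprint pairs, overlap counting as zero. The published 36-bp
  ETS–CTCF figure does not define its metric (center vs edge, mean vs
  median); edge-to-edge with a mean summary is our documented choice.
* **Signal contrasts** on shared footprints use paired two-sided Wilcoxon
  signed-rank tests against a reference cell type, with the signal matrix
  returned sorted by occupancy posterior for heatmap display.

## Contact maps, balancing, and APA

Knight–Ruiz balancing finds weights `w` with
`diag(w) M diag(w)` having equal unmasked row sums. The implementation is
the Knight–Ruiz Newton iteration with conjugate-gradient inner steps;
rows with fewer than 10 nonzeros are masked first (standard for sparse
Hi-C/Low-C bins), the matrix is pre-scaled so entries are O(1), and an
iterated-proportional-scaling fallback runs if the Newton path stalls
(reported via a message). Convergence is verified against the requested
tolerance; the suite requires a row-sum coefficient of variation below
1e-5 on dense 500 x 500 maps and exact scale covariance.

APA aggregates 21 x 21 submatrices (±10 bins, i.e. ±250 kb at 25 kb)
centered on loop anchor pairs, excluding loops whose neighborhood crosses
the diagonal or matrix edge (excluded rather than padded, to avoid
decay-gradient contamination). The corner is the 6 x 6 lower-left block —
high anchor-1 offsets x low anchor-2 offsets, the corner toward the
diagonal, following the Juicer convention — giving the 36 corner bins
used both for P2LL and for the corner-background contrast.

One numerical decision deserves emphasis: the aggregate is computed on
**distance-normalized** balanced values (observed divided by the
per-diagonal mean over unmasked bins). On raw balanced values the
lower-left corner sits systematically closer to the diagonal than the
center, so even a loop-free decay matrix would give P2LL well below 1
(about 0.56 in our simulations); after observed/expected normalization a
constant matrix gives P2LL exactly 1 and loop-free maps give P2LL ≈ 1, so
the score reads as fold enrichment. `normalize = "balanced"` restores the
raw behavior if wanted.

The corner contrast z-standardizes each corner distribution within itself
and compares the two standardized distributions with a two-sided Student's
t-test, reporting the standardized center (peak) values separately. Note
that within-sample standardization removes pure mean shifts by
construction — the test can only detect shape differences, which matches
its published use as a check that background distributions do not differ.

## Survival analyses

The per-sample ranking metric is the sample's expression minus the cohort
mean per gene (log2 scale), i.e. a per-sample log fold change versus the
cohort average, with per-study gene means aligned to the overall mean
first when a merged multi-study cohort is analyzed. The original
per-sample construction is unstated; this metric is the package's
documented choice and the machinery accepts any named metric vector, so
alternatives (per-gene z-scores, within-sample ranks) can be supplied
directly.

Preranked GSEA is the classical weighted Kolmogorov–Smirnov running sum
(hits weighted by `|metric|^weight`, default weight 1; misses uniform),
the ES being the signed extremum. The null permutes gene-set labels;
NES = ES / mean(|null ES| of matching sign) and the permutation p is
one-sided within sign, as in standard GSEA implementations. The
categorical call (enriched / depleted / neutral) uses NES sign and
nominal p < 0.05 — our operationalization of "enrichment or depletion".
The unweighted statistic satisfies exact complement antisymmetry, which
the suite asserts, and the ES is cross-checked against an independent
implementation (fgsea) in the tests only; the package never delegates the
statistic to it.

Youden's J threshold scans midpoints of sorted unique scores, calling
`score >= threshold` positive, and breaks ties toward the lower
threshold; it always equals exhaustive grid search (asserted in tests).
Thresholding uses the binary mortality flag, not time-dependent ROC — the
published description ("maximizing sensitivity and specificity on
mortality") is compatible with both, and the simpler reading is
implemented.

Kaplan–Meier curves, Mantel–Cox log-rank tests and Cox models are
delegated to the `survival` package (the standard implementation such
analyses cite), with Efron tie handling; the trend test for more than two
ordered groups is the score test of a Cox model on group scores 1..k.
Follow-up truncation is administrative censoring at the cutoff day.
Marginal hazard-ratio curves over an exposure grid use the delta method
on the fitted coefficient (and optional exposure-by-age interaction)
variance. The CRISPR-essentiality contrast splits cell lines at
`log2(RPKM + 1) = 1` — boundary assigned to the high group — and reports
`mean effect(high) - mean effect(low)` per gene, negative meaning
stronger essentiality with high expression.

## The synthetic-data generators

Every generator is a pure function of its configuration and seed, emits
its planted truth alongside the data, and the truth is consumed only by
tests — never by pipeline stages.

* **Single-cell counts**: negative binomial (dispersion 0.5) around
  per-gene base means that are log-normal with median 2 counts per cell —
  emulating the well-expressed gene stratum on which subtle perturbation
  effects are discoverable — with log-normal per-cell size factors
  (sd 0.3 on the log scale) and mean-dependent extra dropout. Planted DE
  genes (default 5% at |log2FC| = 1, alternating sign) shift the raw mean
  in condition B. What this does *not* model: ambient RNA, doublets,
  batch structure, UMI saturation, or the long tail of near-undetected
  genes; recovery rates on real data with many lowly expressed genes will
  be lower than on these simulations.
* **Lineage profiles**: Gaussian log2 profiles with a planted set that
  decreases linearly from the HSC column (3 log2 units across 20 cell
  types by default).
* **Multiome**: genes spread across up to 10 chromosomes (so trans null
  pairs exist), one candidate peak per gene within the 500-kb window plus
  background peaks; planted pairs share a latent population factor with
  loading `sqrt(link_r)`, giving correlation ≈ `link_r` across 18
  populations.
* **Footprint landscape**: per-cisRE TF presence, with planted pairs
  drawn from the exact 2x2 joint distribution solving the requested odds
  ratio at the shared base rate; per-site cut counts are Poisson with
  5-fold cleavage protection inside the motif.
* **Contact maps**: Poisson counts around `scale * d^(-1)` decay with a
  3x3 Gaussian focal enrichment kernel at loop pixels, multiplied by the
  per-condition strength; two conditions share the decay model.
* **Cohort**: Gaussian log2 expression with per-study offsets, network
  genes up-shifted by 1.5 log2 units in enriched patients (chosen so the
  per-sample enrichment call reaches the specified sensitivity), constant
  baseline hazard 0.001/day, hazard multiplied by the planted ratio for
  enriched patients, independent exponential censoring calibrated to the
  requested censoring fraction. The constant-hazard (exponential) baseline
  keeps closed-form sanity checks possible; age and sex are generated as
  covariates but carry no effect by default, so Cox adjustment can be
  exercised without confounding the planted signal.

Passing tests on these simulations demonstrate internal statistical
correctness (calibration of nulls, power under planted effects, exactness
against enumeration oracles) — not that the pipeline reproduces any
particular published gene list or hazard ratio, which would require the
original deposited datasets.

## Problem sizes and runtimes in the shipped tests

The suite exercises: 2 x 1,000 cells x 2,000 genes for the permutation
null (100 permutations); 2 x 2,000 cells for planted-DE recovery; 500 x
500 dense maps for balancing; 100 simulated map pairs (400 bins at 25 kb,
20 loops) for the P2LL ordering; 100 seeds x 250 permutations for
occupancy calibration; and 200 replicates of the full 400-patient cohort
pipeline (100 GSEA permutations per sample) for hazard-ratio coverage.
These sizes were chosen as the smallest at which the planted effects are
comfortably in the asymptotic regime the corresponding statistics assume.

## Known limitations

* The hurdle test omits MAST's cellular-detection-rate covariate and any
  shrinkage; gene lists will differ from Seurat+MAST runs.
* cisRE–gene link scoring is a reconstruction; the original framework's
  per-population weighting and distance decay are unavailable.
* Footprint *calling* (posterior estimation from cut counts) is out of
  scope; posteriors are inputs.
* Loop calling, TAD calling and read-level processing are out of scope;
  loops and maps are consumed, not derived.
* The per-sample GSEA metric and the signature-score scaling are
  documented package choices where the published text is silent.
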