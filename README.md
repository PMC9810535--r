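# hemenet

Tools for deriving a cis-regulatory gene network that maintains
hematopoietic stem cells (HSCs) from perturbation single-cell RNA-seq,
characterizing its regulatory architecture (cisRE–gene links,
transcription-factor footprints, chromatin loops), and testing its
clinical relevance in acute myeloid leukemia (AML) survival cohorts. The
package is aimed at computational biologists working in regulatory
genomics and hematopoiesis who want each of these analysis stages as a
tested, reusable function rather than a one-off script.

## What it implements

* **Hurdle differential expression** for two-condition single-cell
  counts: per gene, a likelihood-ratio test combining a Bernoulli
  component on detection and a Gaussian component on log-normalized
  nonzero values, referred to χ² with 2 df; Bonferroni adjustment;
  network gene sets called at log₂FC > 0.05 and adjusted p < 1e−20;
  label-permutation nulls and pseudobulk Spearman concordance as
  validation.
* **Lineage enrichment**: for gene set *i* and cell type *j*,
  *z*ᵢⱼ = (yᵢⱼ − mean yᵢⱼ⁽ᴾ⁾) / sd yᵢⱼ⁽ᴾ⁾ over 1,000 same-size permuted
  gene sets (exact subset enumeration when feasible).
* **cisRE–gene linking**: merged cisRE catalog across populations;
  Pearson correlation of accessibility and expression across populations
  within ±500 kb of the TSS; trans-pair empirical null; BH adjustment;
  HSC-open network selection with score r × minmax(HSC accessibility);
  PFM motif similarity with offset/orientation search and permutation p.
* **Footprint statistics**: aggregate Tn5 cleavage profiles; pairwise TF
  co-occurrence in cisREs by two-sided hypergeometric test; occupancy
  enrichment against 1,000 genome-wide peak re-placements; edge-to-edge
  footprint spacing; paired Wilcoxon signed-rank signal contrasts across
  lineages.
* **Chromatin loops**: Knight–Ruiz balancing (Newton/CG iteration with a
  proportional-scaling fallback); aggregate peak analysis over ±250 kb at
  25-kb bins with the peak-to-lower-left ratio
  P2LL = center / mean(6×6 lower-left corner) on distance-normalized
  balanced signal; loop classification by CTCF anchors and network
  cisREs; corner-background t-contrasts.
* **AML survival**: per-sample preranked GSEA (weighted
  Kolmogorov–Smirnov running sum, sign-stratified permutation NES and p);
  Youden's J optimal thresholds; Kaplan–Meier with Mantel–Cox log-rank
  and trend tests; Cox proportional hazards (Efron ties) with marginal
  hazard curves by age; expression-stratified CRISPR (CERES)
  differential essentiality.
* **Synthetic data** with planted ground truth for every input format the
  pipeline reads (MTX+TSV, BED/BEDPE, contact-map triplets, GMT, cohort
  TSV), so the whole chain runs and is tested offline.

## Worked example

Simulate a perturbation experiment with 5% planted DE genes at
|log₂FC| = 1, discover the network, and validate it:

```r
library(hemenet)

cfg <- sc_sim_config(n_cells_per_condition = 1000, n_genes = 1000, seed = 42)
sim <- gen_sc_counts(cfg)
norm <- normalize_log(sim$counts)
de   <- hurdle_de(norm, sim$cell_meta$condition)   # A = control, B = perturbed
net  <- call_network(de)
net
#> network gene sets (reference = A): 20 down, 25 up

head(de[order(de$adj_p), ], 3)
#>          gene    log2fc            p detect_rate_a detect_rate_b        adj_p
#> 396 gene_0396 -1.051341 2.407983e-71         0.924         0.970 2.405575e-68
#> 956 gene_0956 -1.082234 3.932208e-70         0.857         0.943 3.928276e-67
#> 975 gene_0975  1.050363 5.560234e-69         0.981         0.936 5.554674e-66

table(permutation_de_null(norm, sim$cell_meta$condition, n_perm = 20, seed = 7))
#>  0
#> 20          # no permutation yields a single called gene

pb <- pseudobulk_concordance(sim$counts, sim$cell_meta$condition,
                             setNames(de$log2fc, de$gene), seed = 8)
#> pseudobulk Spearman rho = 0.854 (perm p = 0.0050)
```

The `down` set contains genes higher in the control (lost after
perturbation); the permutation null shows the thresholds admit nothing on
exchangeable data; the pseudobulk fold changes rank-agree with the
single-cell ones.

Score the planted stemness-graded set across 20 lineages, then compare
loop enrichment between two conditions:

```r
lp <- gen_lineage_profiles(seed = 9)
lz <- lineage_zscore(lp$profiles, lp$truth, n_perm = 1000, seed = 10)
head(lz[order(-lz$z), c("cell_type", "y_obs", "z")], 3)
#>   cell_type    y_obs        z
#> 1       HSC 7.992249 14.25727   # enrichment peaks in the HSC column
#> 2    pop_01 7.909177 13.99334
#> 3    pop_02 7.654608 12.55503

set.seed(5)                                        # 12 loops, 0.75-1.4 Mb spans
d <- sample(30:55, 12, replace = TRUE); i <- sample(12:330, 12)
loops <- data.frame(chrom1 = "chr1", start1 = (i - 1) * 25e3, end1 = i * 25e3,
                    chrom2 = "chr1", start2 = (i + d - 1) * 25e3,
                    end2 = (i + d) * 25e3,
                    strength_a = 1, strength_b = 2)
maps <- gen_contact_map(loops = loops, seed = 6)   # strengths B:A = 2
apa(kr_balance(maps$A), loops)
#> APA over 12 loops (0 excluded): P2LL = 1.827
apa(kr_balance(maps$B), loops)
#> APA over 12 loops (0 excluded): P2LL = 2.711
```

P2LL reads as fold enrichment of the loop pixel over the local
background; the condition with doubled planted strength shows the larger
score, while the corner backgrounds do not differ (`corner_contrast`
gives t = 0.00, p = 1.00 here).

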