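# rootatlas

Tools for the computational backbone of rice-root single-cell studies of
soil and compaction stress: consensus cell-type annotation of protoplast
scRNA-seq, developmental-stage assignment against bulk zone profiles,
replicate-aware pseudobulk differential expression with the field's DEG
filter rules, hypergeometric gene-set enrichment — plus the two
quantitative wet-lab analyses that accompany such studies, radial
water-loss decay fitting and Gaussian-mixture segmentation of
phonon-microscopy (Brillouin) maps. A seeded synthetic-data module
generates every input with known ground truth, so the whole pipeline is
testable on a laptop without touching sequencing archives.

## Who this is for

Plant single-cell groups who need a transparent, dependency-light
re-implementation of this annotation/DE scheme they can validate end to end;
and anyone who wants the water-loss and phonon quantifications as plain,
tested R functions.

## The methods in brief

**Consensus annotation.** Cells are embedded by PCA (50 components),
clustered on a shared-nearest-neighbour graph (k = 15, Jaccard weights) by
modularity community detection at a coarse and a fine resolution. For each
clustering, per-gene z-scores of cluster mean expression are averaged over
each cell type's validated markers; a cluster gets the argmax type when the
best average z ≥ z_min. Cells labelled identically at both resolutions form
the consensus; per-type reference profiles are averaged over consensus
cells, and remaining cells are assigned by Pearson correlation with those
profiles on the marker genes. Developmental stages come from argmax Pearson
correlation against bulk profiles of meristem / elongation / maturation
zones.

**Pseudobulk DE.** Raw counts are summed per (sample, cell type); pairs
with < 10 cells are excluded. Per gene, a negative-binomial model with
library-size offsets is fitted to the two conditions; method-of-moments
dispersions are shrunk toward the common median, and the likelihood-ratio
statistic is referred to F(1, d) with moderated denominator df. A gene is a
DEG when FDR ≤ 0.05, |fold change| ≥ 1.5 and detection frequency ≥ 10 % in
at least one condition (all comparisons inclusive). Enrichment is the
one-tailed hypergeometric test with BH correction.

**Water loss.** Remaining water follows the two-phase decay
W(t) = plateau + span_f·e^(−k_f t) + span_s·e^(−k_s t); t50 solves
W(t) = W(0)/2 by bisection. Mass-loss rates convert to radial flux
(rate / 18.015 g mol⁻¹ × 10⁶) / (π·d·L) in µmol m⁻² s⁻¹.

**Phonon maps.** f_B = 2nv/λ_probe and M = ρv². Per-pixel (Δf_B, α_B)
clouds are segmented by a two-component bivariate Gaussian mixture (EM,
k-means init, monotone log-likelihood asserted); "roughly 70 % confidence"
regions are Mahalanobis/χ²₂ regions; groups are compared with Yuen's
trimmed-mean t-test (trim 0.2; trim 0 ≡ Welch).

## Worked example

```r
library(rootatlas)
cfg   <- atlas_config(seed = 7)            # 8 root cell types, 4 stages
atlas <- generate_atlas(cfg)
qc    <- qc_filter(atlas$counts)           # 5% mito rule, top-1% UMI trim
pp    <- generate_protoplast_profiles(cfg)
cm    <- exclude_genes(qc$counts,
          mito        = subset(qc$counts$gene_meta, is_mito)$gene_id,
          chloroplast = subset(qc$counts$gene_meta, is_chloroplast)$gene_id,
          protoplast  = protoplast_gene_screen(pp$protoplasted, pp$control))
expr  <- normalize_counts(cm)
labs  <- annotate_cells(expr, atlas_marker_set(cfg),
                        zones = generate_bulk_zones(cfg)[rownames(expr$values), ],
                        seed = 1)
```

prints

```
count_matrix: 1500 genes x 2000 cells; 9 samples, 3 conditions
QC removed 124 cells (105 mito-fraction, 19 top-UMI)
consensus_labels: 1876 cells, 1876 annotated (1706 by consensus, 170 by correlation)
type accuracy 0.995, ARI 0.989, stage accuracy 0.999
```

i.e. 105 cells fell to the 5 % mitochondrial rule and 19 to the top-UMI
trim; 91 % of the surviving cells were confidently annotated by the
dual-resolution consensus and the rest by marker correlation, recovering
the planted labels almost perfectly (accuracies computed against
`atlas$truth`). The biophysics side:

```r
fit <- fit_two_phase_decay(generate_waterloss(
  decay_fit(plateau = 20, span_fast = 50, span_slow = 30,
            k_fast = 0.15, k_slow = 0.01),
  n_points = 60, dt = 0.5, noise_sd = 1, seed = 2))
time_to_half_loss(fit)

map <- generate_phonon_map(means = list(c(0, 1), c(6, 4)),
                           covs = list(diag(2), diag(2)),
                           weights = c(0.55, 0.45), grid = c(100, 100), seed = 3)
gmm <- fit_gmm2(map, seed = 1)
confidence_membership(gmm, level = 0.70)$means$cell_wall
```

prints

```
two-phase decay: plateau 0.000 + 47.442 exp(-0.1631 t) + 52.647 exp(-0.00747 t)  [rss 75.8]
t50 = 16.18 min
gmm2: weights 0.551/0.449; background dfb -0.00898, cell_wall dfb 5.99; loglik -3.549e+04
cell wall: mean dfb 5.997, alpha 4.009 over 3113 pixels in the 70% region
```

— the fitted decay recovers the planted half-loss time (16.1 min planted)
from a 1 %-noise series, and the mixture recovers the planted cell-wall
component (Δf_B = 6, α_B = 4) to three decimals.

## Command line

`inst/cli/rootatlas` exposes `simulate`, `qc`, `annotate`, `de`, `enrich`,
`waterloss` and `phonon` subcommands over the same functions, reading and
writing 10x-style MTX triplets, TSV tables and CSV grids.

See `vignettes/rootatlas-methods.Rmd` for the full model description,
parameter choices and limitations.
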