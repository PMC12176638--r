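---
title: "rootatlas: models, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootatlas: models, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific and numerical decisions behind each
stage of the package, in the spirit of the methods sections of the mature
expression-analysis packages: what is modelled, what is assumed, which
knobs matter, and what a green test does and does not establish.

## The synthetic world

The generator (`atlas_config()` / `generate_atlas()`) replaces deposited
sequencing data with a stated statistical world that has the features the
downstream stages rely on. Counts are negative binomial per gene and cell,

$$y_{gc} \sim \mathrm{NB}(\mu_{gc},\ \phi_g), \qquad
\log_2 \mu_{gc} = b_g + T_{g,t(c)} + m_g\,[t(c) = \mathrm{home}(g)]
+ s_g\,(z(c) - \bar z) + \delta_{g,\mathrm{cond}(c)} + \log_2 \ell_c
+ \log_2 \pi_g,$$

with baseline abundance $b_g \sim N(0, 1.2^2)$, per-(gene, type) identity
programs $T_{g,t} \sim N(0, \texttt{type\_log2\_sd}^2)$, marker elevation
$m_g = \texttt{marker\_log2\_effect}$ in the marker's home type only, a
linear developmental gradient with per-gene slope
$s_g \sim N(0, \texttt{stage\_log2\_sd}^2)$ over the ordered stage index,
planted condition-specific shifts $\delta$, a log-normal library-size
factor $\ell_c$, and a gene-level logistic dropout thinning
$\pi_g = \mathrm{logit}^{-1}(\texttt{slope}(b_g - \texttt{midpoint}))$
applied to the mean before sampling. Dispersions are
$\phi_g = \texttt{nb\_dispersion}\cdot\mathrm{Gamma}(4,4)$.

Choices worth defending:

* **Type programs (`type_log2_sd = 0.4`).** Cell identity in real tissue is
  a transcriptome-wide program, of which validated markers are only the
  curated tip. A world in which types differ *only* on a handful of marker
  genes is not clusterable by any method that does not already know the
  markers — PCA and graph clustering would recover the stage gradient
  instead — so such a world cannot support the annotation scheme it is
  meant to exercise. 0.4 log2 units is deliberately modest relative to the
  marker effect (2 log2).
* **Stage gradient (`stage_log2_sd = 0.5`).** Developmental zones of a root
  tip differ strongly; a per-gene linear trend in log-mean is the simplest
  structure that makes stage assignment well-posed. Marker genes are given
  zero slope: validated markers are curated precisely for developmental
  stability.
* **Dropout at the gene level.** The keep-probability depends on the gene's
  baseline abundance, not the cell-specific mean, so planted fold ratios
  survive thinning exactly; this keeps generator truth usable as an oracle.
* **Mito-high cells.** Organellar baselines are lowered by 1.5 log2 so
  healthy cells sit at ~1–2 % mitochondrial fraction; the planted
  low-quality class elevates mito genes by `mito_high_log2 = 3` (8-fold),
  placing it clearly above the 5 % threshold. The QC recall test depends on
  this separation being, as in real data, gross rather than marginal.
* **No doublets, no empty droplets, no batch structure** — all out of scope
  of the pipeline stages exercised here, hence not simulated. A green
  annotation test therefore says nothing about doublet robustness or
  cross-chemistry integration.

## Preprocessing

The cell filter applies the 5 % mitochondrial-fraction rule strictly
(`> mito_max` removes), then trims the top `ceiling(0.01 · n)` cells by UMI
count — in that order, mirroring the usual "quality filter, then outlier
trim" sequence. The protoplasting screen flags genes with
$|\log_2((a + c)/(b + c))| \ge 2$ on CPM with pseudocount $c = 0.5$
(inclusive comparison); the pseudocount is an argument because the exact
boundary examples of the rule are only meaningful at $c \to 0$.

Normalization is median-library scaling + log1p. This removes the
library-size scaling exactly on the linear scale (every cell's rescaled
total equals the median library, which the tests assert). One caution: the
*log-scale* column mean still correlates with sequencing depth through the
number of detected genes. That is a property of any log transform of
sparse counts — regression-based methods exist precisely because of it —
and downstream stages here use the values only through correlations and
cluster means, which are insensitive to it.

## Annotation

The dual-resolution consensus follows the scheme: cluster coarse and fine,
label each cluster by the average across-cluster z-score of its marker
genes (threshold `z_min = 0.5`; ties broken by marker count then name, and
flagged), keep cells labelled identically at both resolutions, average
consensus cells into reference profiles, and annotate the remainder by
Pearson correlation with those profiles.

Two design points were settled by experiment rather than taken as given:

* **Resolution choice.** "Reasonable cluster numbers" is operationalized
  as: low = the smallest resolution on a fixed ladder giving at least as
  many clusters as marker types, high = the smallest *strictly finer*
  resolution giving at least three times that. The strictness matters: if
  one resolution satisfies both rules the two clusterings are identical and
  the consensus degenerates to a single clustering with no error
  cancellation.
* **Correlation gene set and scope.** The correlation stage uses the
  marker genes and, by default, only fills in cells the consensus left
  unannotated (`overturn_consensus = TRUE` restores full re-annotation).
  Measured on the synthetic world, re-annotating every cell on all genes
  reaches only ~0.55 accuracy: single-cell profiles are dominated by the
  shared abundance baseline and the stage gradient, so the small
  between-profile differences that encode type drown; worse, when
  consensus coverage is stage-skewed the per-type profiles acquire stage
  flavours that mislead systematically. Markers are type-specific and
  stage-stable by construction (and by curation, in real data), and the
  consensus labels they confirm at two resolutions are strictly more
  reliable than a per-cell correlation, so overturning them is not a
  default.

Stage assignment is argmax Pearson correlation against bulk zone profiles,
computed on all shared genes — here the gradient *is* the signal.

## Pseudobulk differential expression

Counts are summed per (sample, cell type); pairs with fewer than 10 cells
are excluded (small pairs destabilize dispersion estimation; the threshold
is exposed). The test is a negative-binomial likelihood-ratio test with
library-size offsets. Per-gene dispersions come from method of moments on
the two-group fit with an $n/(n-2)$ correction, then shrink toward the
common median with weight $w$:
$\tilde\phi_g = (1-w)\hat\phi_g + w\,\hat\phi_{\mathrm{common}}$.

The LR statistic is referred to an $F(1, d)$ distribution with
$d = (n - 2)/(1 - w)$ rather than $\chi^2_1$: with three replicates per
condition the $\chi^2$ reference is visibly anticonservative, and $d$
counts the residual degrees of freedom plus the prior information implied
by the shrinkage ($\chi^2$ is recovered as $w \to 1$). The default
$w = 0.5$ (hence $d = 8$ at 3 + 3 replicates) was fixed by the null
simulation the package itself ships: 2,000-gene global-null pseudobulk
runs, requiring a near-nominal filter-pass rate and KS-uniform p-values.
Fold changes are computed on offset-adjusted CPM with pseudocount 0.5 and
the DEG rules (FDR ≤ 0.05, |FC| ≥ 1.5, detection ≥ 10 % in either
condition) are all inclusive; detection frequency is pooled per condition.
Enrichment is the upper-tail hypergeometric probability with BH correction
across terms (a g:SCS-style correction is tool-specific and not
reproduced).

## Water loss

Remaining water is modelled as
$W(t) = \mathrm{plateau} + S_f e^{-k_f t} + S_s e^{-k_s t}$ with
non-negative amplitudes and $k_f > k_s$ enforced by phase swapping; the
fit is constrained least squares from a 3 × 3 multistart over rate guesses
(crude half-loss rate × {1, 3, 10}, slow/fast ratio {0.02, 0.1, 0.3}),
with a derivative-free fallback when the solver errors. $t_{50}$ solves
$W(t) = W(0)/2$ by bisection to $10^{-6}$ min on the strictly decreasing
model; a raw-interpolation variant (`t50_interpolate`) is provided because
"time to half loss" can be read either way. Flux conversion fixes the
molar mass of water at 18.015 g mol⁻¹ and uses the lateral cylinder
surface $\pi d L$. The default synthetic decay (plateau 20 %, spans
50/30 %, rates 0.15/0.01 min⁻¹, $t_{50} \approx 16$ min) sits in the range
reported for excised rice root segments (half-loss times of roughly a
quarter of an hour).

## Phonon maps

$f_B = 2nv/\lambda_{\mathrm{probe}}$ and $M = \rho v^2$ are implemented as
stated; no attempt is made to estimate absolute moduli from measured maps
(that requires per-pixel $n$ and $\rho$). Segmentation is a two-component
bivariate Gaussian mixture fitted by EM with 2-means initialization on
standardized coordinates, a small covariance ridge, and an internal
assertion that the log-likelihood never decreases — a violated assertion
is an error, so every fitted object has passed the monotonicity check.
The component with higher mean $\Delta f_B$ is labelled "cell wall" (the
stiffer phase); this automatic rule replaces the manual
morphology-based labelling and can be overridden by the caller. The
"roughly 70 % confidence" summary is implemented exactly: a pixel is in a
component's region iff it is assigned by maximum responsibility and its
squared Mahalanobis distance is within $\chi^2_2(0.70) = -2\ln 0.30$.
Group comparison uses Yuen's t-test on 20 %-trimmed means with winsorized
variances and Welch–Satterthwaite df; trim 0 reduces exactly to Welch.

## Degenerate inputs and tie-breaking

Constant-expression cells have undefined correlations and stay
unannotated with a recorded reason; identical zone profiles or equal
correlations are broken deterministically (lexicographic) and flagged;
all-zero genes get p = 1 and log2FC = 0; a collapsed mixture component is
regularized rather than inverted; over-trimming and empty strata are
errors, not NaNs.

## What the tests establish — and what they cannot

The acceptance suite shows that on the stated world the pipeline recovers
planted types (ARI ≥ 0.9), stages (≥ 90 %), planted DEGs (recall ≥ 0.8 with
the planted cell types top-ranked), that the DE test is calibrated at the
global null, and that the biophysics fits recover planted parameters at
stated tolerances. It does not establish performance on real droplet data
with doublets, ambient RNA, batch effects, unbalanced type abundances or
marker sets of uneven quality; those axes are deliberately outside the
simulated world.
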