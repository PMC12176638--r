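Package: rootatlas
Title: Cell-Type Annotation, Pseudobulk Differential Expression and
    Biophysical Quantification for Rice Root Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@rootatlas.dev",
           role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used in
    rice root single-cell studies of soil compaction stress: quality filtering
    and gene-exclusion screens for protoplast scRNA-seq, dual-resolution
    consensus cell-type annotation with marker z-scores and correlation-based
    re-annotation, developmental-stage assignment against bulk zone profiles,
    pseudobulk negative-binomial differential expression with detection-
    frequency filters, hypergeometric gene-set enrichment, two-phase
    exponential decay fitting of radial water-loss series, and two-component
    Gaussian-mixture segmentation of phonon-microscopy (Brillouin) maps with
    Yuen's trimmed-mean t-test. A seeded synthetic-data module generates
    count matrices, bulk zone profiles, water-loss series and phonon maps
    with known ground truth so that every stage is testable without access
    to sequencing archives.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
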