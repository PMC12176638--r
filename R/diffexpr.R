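#' Differential-expression thresholds
#'
#' The DEG calling rules: FDR-adjusted p <= fdr_max, absolute (linear) fold
#' change >= fc_min, and detection frequency >= det_min in at least one of
#' the compared conditions; pseudobulk pairs with fewer than
#' \code{min_cells} cells are excluded from testing.
#'
#' @param fdr_max maximum BH-adjusted p (default 0.05).
#' @param fc_min minimum linear fold change (default 1.5).
#' @param det_min minimum detection frequency (default 0.10).
#' @param min_cells minimum cells per (sample, type) pseudobulk pair
#'   (default 10).
#' @return validated list of class \code{de_thresholds}.
#' @export
de_thresholds <- function(fdr_max = 0.05, fc_min = 1.5, det_min = 0.10,
                          min_cells = 10) {
  if (fdr_max <= 0 || fdr_max >= 1) stopf("fdr_max must lie in (0, 1)")
  if (fc_min < 1) stopf("fc_min must be >= 1 (linear scale)")
  if (det_min < 0 || det_min > 1) stopf("det_min must lie in [0, 1]")
  if (min_cells < 1) stopf("min_cells must be >= 1")
  structure(list(fdr_max = fdr_max, fc_min = fc_min, det_min = det_min,
                 min_cells = as.integer(min_cells)),
            class = "de_thresholds")
}

#' Aggregate a count matrix into pseudobulk pairs
#'
#' Sums raw counts gene-wise over all cells of each (sample, cell type)
#' pair, excluding unannotated cells; per-pair cell counts and conditions
#' are recorded and pairs below a cell-count floor are flagged.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param labels a \code{\link{consensus_labels}} or named character vector
#'   (cell -> type) covering the matrix's cells.
#' @param min_cells flag pairs with fewer cells than this (default 10).
#' @return object of class \code{pseudobulk_table}: \code{counts} (genes x
#'   pairs integer matrix) and \code{pairs} (sample, cell_type, condition,
#'   n_cells, small).
#' @export
aggregate_pseudobulk <- function(counts, labels, min_cells = 10) {
  type <- if (inherits(labels, "consensus_labels")) labels$type else labels
  if (!all(colnames(counts$counts) %in% names(type)))
    stopf("labels do not cover all cells of the matrix")
  type <- type[colnames(counts$counts)]
  keep <- type != UNANNOTATED & !is.na(type)
  if (!any(keep)) stopf("no annotated cells to aggregate")
  sample <- counts$cell_meta$sample
  grp <- factor(paste(sample, type, sep = "\r"))[keep]
  ind <- Matrix::sparseMatrix(i = which(keep), j = as.integer(grp),
                              x = 1, dims = c(ncol(counts$counts), nlevels(grp)))
  pbm <- as.matrix(counts$counts %*% ind)
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  n_cells <- as.integer(table(grp))
  cond <- counts$cell_meta$condition[match(parts[, 1], counts$cell_meta$sample)]
  colnames(pbm) <- paste(parts[, 1], parts[, 2], sep = ".")
  pairs <- data.frame(pair = colnames(pbm), sample = parts[, 1],
                      cell_type = parts[, 2], condition = cond,
                      n_cells = n_cells, small = n_cells < min_cells,
                      stringsAsFactors = FALSE)
  structure(list(counts = pbm, pairs = pairs), class = "pseudobulk_table")
}

#' @export
print.pseudobulk_table <- function(x, ...) {
  cat(sprintf("pseudobulk_table: %d genes x %d (sample, type) pairs; %d flagged small\n",
              nrow(x$counts), ncol(x$counts), sum(x$pairs$small)))
  invisible(x)
}

## negative-binomial log-likelihood, vectorized over a genes x samples matrix
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  pois <- phi < 1e-8
  ll <- matrix(0, nrow(y), ncol(y))
  if (any(pois)) {
    yy <- y[pois, , drop = FALSE]; mm <- mu[pois, , drop = FALSE]
    ll[pois, ] <- yy * log(mm) - mm - lgamma(yy + 1)
  }
  if (any(!pois)) {
    yy <- y[!pois, , drop = FALSE]; mm <- mu[!pois, , drop = FALSE]
    r <- 1 / phi[!pois]
    ll[!pois, ] <- lgamma(yy + r) - lgamma(r) - lgamma(yy + 1) +
      r * log(r / (r + mm)) + yy * log(mm / (r + mm))
  }
  rowSums(ll)
}

## Fisher-scoring fit of per-gene NB rates with library-size offsets:
## mu_gj = q_g * s_j. Returns the rate vector q (genes).
nb_fit_rate <- function(y, s, phi, iter = 50L) {
  q <- pmax(rowSums(y) / sum(s), 1e-12)
  eta <- log(q)
  for (it in seq_len(iter)) {
    mu <- exp(eta) %o% s
    wden <- 1 + phi * mu
    U <- rowSums((y - mu) / wden)
    J <- rowSums(mu / wden)
    step <- U / pmax(J, 1e-12)
    step <- pmax(pmin(step, 5), -5)
    eta <- eta + step
    if (max(abs(step)) < 1e-12) break
  }
  exp(eta)
}

## method-of-moments NB dispersion from alternative-model (per-group) means,
## with an n/(n - p) small-sample correction on the squared residuals
mom_dispersion <- function(y, mu, n_params) {
  n <- ncol(y)
  corr <- n / max(n - n_params, 1)
  num <- rowSums((y - mu)^2 * corr - mu)
  den <- rowSums(mu^2)
  pmin(pmax(ifelse(den > 0, num / den, 0), 0), 10)
}

#' Pseudobulk negative-binomial differential-expression test
#'
#' Replicate-aware two-condition test per gene for one cell type: NB model
#' with library-size offsets, per-gene method-of-moments dispersion shrunk
#' toward the common (median) dispersion, and a moderated likelihood-ratio
#' test for the condition effect: the LR statistic is referred to an
#' F(1, d) distribution whose denominator degrees of freedom
#' d = residual df / (1 - shrink_weight) count both the per-gene residual
#' information and the prior information implied by the shrinkage (the
#' chi-squared reference is the shrink_weight -> 1 limit). Log2 fold
#' changes come from
#' offset-adjusted group mean rates (CPM scale) with a symmetric
#' pseudocount.
#'
#' @param pb a \code{\link{pseudobulk_table}}.
#' @param cell_type cell type to test.
#' @param cond_a,cond_b condition labels; fold change is B over A.
#' @param thresholds a \code{\link{de_thresholds}} (min_cells used here).
#' @param shrink_weight weight of the common dispersion in the shrunk
#'   per-gene estimate, in [0, 1] (default 0.5, chosen by null-simulation
#'   calibration; it also sets the moderated test's denominator df).
#' @param pseudocount CPM pseudocount for fold changes (default 0.5).
#' @return data.frame: gene, log2fc, p_value, plus per-group CPM; attribute
#'   \code{dispersion} carries the shrunken estimates.
#' @export
nb_de_test <- function(pb, cell_type, cond_a, cond_b,
                       thresholds = de_thresholds(), shrink_weight = 0.5,
                       pseudocount = 0.5) {
  if (shrink_weight < 0 || shrink_weight > 1) stopf("shrink_weight must lie in [0, 1]")
  sel <- pb$pairs$cell_type == cell_type &
    pb$pairs$condition %in% c(cond_a, cond_b) &
    pb$pairs$n_cells >= thresholds$min_cells
  pairs <- pb$pairs[sel, , drop = FALSE]
  for (cc in c(cond_a, cond_b))
    if (sum(pairs$condition == cc) < 2)
      stopf("condition %s has < 2 usable pseudobulk pairs for type %s", cc, cell_type)
  y <- pb$counts[, pairs$pair, drop = FALSE]
  s <- colSums(y)
  grp <- pairs$condition == cond_b  # FALSE = A, TRUE = B

  ## group means under the alternative (Poisson fit is the closed form)
  qa0 <- rowSums(y[, !grp, drop = FALSE]) / sum(s[!grp])
  qb0 <- rowSums(y[, grp, drop = FALSE]) / sum(s[grp])
  mu_alt0 <- cbind(qa0 %o% s[!grp], qb0 %o% s[grp])[, order(c(which(!grp), which(grp)))]
  phi_g <- mom_dispersion(y, mu_alt0, n_params = 2)
  expressed <- rowMeans(y) >= 1
  phi_common <- if (any(expressed)) median(phi_g[expressed]) else median(phi_g)
  phi <- (1 - shrink_weight) * phi_g + shrink_weight * phi_common

  qa <- nb_fit_rate(y[, !grp, drop = FALSE], s[!grp], phi)
  qb <- nb_fit_rate(y[, grp, drop = FALSE], s[grp], phi)
  q0 <- nb_fit_rate(y, s, phi)
  ll_alt <- nb_loglik(y[, !grp, drop = FALSE], qa %o% s[!grp], phi) +
    nb_loglik(y[, grp, drop = FALSE], qb %o% s[grp], phi)
  ll_null <- nb_loglik(y, q0 %o% s, phi)
  lr <- pmax(2 * (ll_alt - ll_null), 0)
  df_resid <- ncol(y) - 2
  p <- if (shrink_weight >= 1) pchisq(lr, df = 1, lower.tail = FALSE)
       else stats::pf(lr, 1, df_resid / (1 - shrink_weight), lower.tail = FALSE)
  cpm_a <- qa * 1e6; cpm_b <- qb * 1e6
  lfc <- log2((cpm_b + pseudocount) / (cpm_a + pseudocount))
  allzero <- rowSums(y) == 0
  p[allzero] <- 1; lfc[allzero] <- 0
  out <- data.frame(gene = rownames(y), log2fc = lfc, p_value = p,
                    cpm_a = cpm_a, cpm_b = cpm_b, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dispersion") <- phi
  attr(out, "pairs") <- pairs
  out
}

#' Detection frequency of a gene in a stratum
#'
#' Fraction of cells of one (cell type, condition) stratum with a nonzero
#' count for the gene.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param labels per-cell type labels (vector or
#'   \code{\link{consensus_labels}}).
#' @param gene gene id.
#' @param cell_type,condition stratum definition.
#' @return fraction in \[0, 1\].
#' @export
detection_frequency <- function(counts, labels, gene, cell_type, condition) {
  type <- if (inherits(labels, "consensus_labels")) labels$type else labels
  sel <- type[colnames(counts$counts)] == cell_type &
    counts$cell_meta$condition == condition
  if (!any(sel)) stopf("empty stratum: %s / %s", cell_type, condition)
  mean(counts$counts[gene, sel] > 0)
}

## vectorized detection frequencies for all genes in one stratum
detection_freq_all <- function(counts, type_vec, cell_type, condition) {
  sel <- type_vec == cell_type & counts$cell_meta$condition == condition
  if (!any(sel)) return(setNames(rep(NA_real_, nrow(counts$counts)),
                                 rownames(counts$counts)))
  Matrix::rowSums(counts$counts[, sel, drop = FALSE] > 0) / sum(sel)
}

#' Per-cell-type differential expression between two conditions
#'
#' Runs the pseudobulk NB test for every cell type with enough replicates,
#' attaches pooled per-condition detection frequencies, adjusts p-values by
#' Benjamini-Hochberg within each cell type, and evaluates the DEG filter
#' flags (all comparisons inclusive).
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param labels per-cell type labels.
#' @param cond_a,cond_b conditions compared (fold change B over A).
#' @param thresholds a \code{\link{de_thresholds}}.
#' @param shrink_weight passed to \code{\link{nb_de_test}}.
#' @return data.frame of class \code{de_result}: gene, cell_type, log2fc,
#'   p_value, fdr, det_a, det_b, passes_filters.
#' @export
de_analysis <- function(counts, labels, cond_a, cond_b,
                        thresholds = de_thresholds(), shrink_weight = 0.5) {
  type <- if (inherits(labels, "consensus_labels")) labels$type else labels
  type <- type[colnames(counts$counts)]
  pb <- aggregate_pseudobulk(counts, type, min_cells = thresholds$min_cells)
  usable <- vapply(unique(pb$pairs$cell_type), function(ty) {
    ok <- pb$pairs$cell_type == ty & !pb$pairs$small
    sum(pb$pairs$condition[ok] == cond_a) >= 2 &&
      sum(pb$pairs$condition[ok] == cond_b) >= 2
  }, logical(1))
  types <- sort(unique(pb$pairs$cell_type)[usable])
  if (!length(types)) stopf("no cell type has >= 2 usable pairs in both conditions")
  res <- lapply(types, function(ty) {
    tt <- nb_de_test(pb, ty, cond_a, cond_b, thresholds, shrink_weight)
    tt$cell_type <- ty
    tt$fdr <- p.adjust(tt$p_value, method = "BH")
    tt$det_a <- detection_freq_all(counts, type, ty, cond_a)[tt$gene]
    tt$det_b <- detection_freq_all(counts, type, ty, cond_b)[tt$gene]
    tt
  })
  out <- do.call(rbind, res)
  out$passes_filters <- out$fdr <= thresholds$fdr_max &
    abs(out$log2fc) >= log2(thresholds$fc_min) &
    pmax(out$det_a, out$det_b) >= thresholds$det_min
  out <- out[, c("gene", "cell_type", "log2fc", "p_value", "fdr",
                 "det_a", "det_b", "passes_filters")]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Apply the DEG filter rules
#'
#' Retains rows with fdr <= fdr_max, |linear fold change| >= fc_min and
#' detection frequency >= det_min in at least one condition; all
#' comparisons inclusive, applied independently per cell type (the FDR is
#' already per-type).
#'
#' @param results a \code{\link{de_analysis}} table.
#' @param thresholds a \code{\link{de_thresholds}}.
#' @return the DEG subset of \code{results}.
#' @export
filter_degs <- function(results, thresholds = de_thresholds()) {
  pass <- results$fdr <= thresholds$fdr_max &
    abs(results$log2fc) >= log2(thresholds$fc_min) &
    pmax(results$det_a, results$det_b) >= thresholds$det_min
  out <- results[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DEG counts per cell type and single-type fraction
#'
#' Counts DEGs per cell type and the fraction of distinct DEGs altered in
#' exactly one cell type (the "cell-type-specific response" statistic).
#'
#' @param degs a filtered DEG table with columns gene and cell_type.
#' @return list: \code{counts} (named, decreasing), \code{unique_fraction}
#'   (NA for an empty table), \code{n_genes} distinct DEGs.
#' @export
deg_summary <- function(degs) {
  if (nrow(degs) == 0)
    return(list(counts = integer(0), unique_fraction = NA_real_, n_genes = 0L))
  counts <- sort(table(degs$cell_type), decreasing = TRUE)
  per_gene <- table(unique(degs[, c("gene", "cell_type")])$gene)
  list(counts = counts,
       unique_fraction = mean(per_gene == 1),
       n_genes = length(per_gene))
}

#' One-tailed hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the realized overlap between the selected genes and the term's
#' genes within the universe, with Benjamini-Hochberg correction across
#' terms.
#'
#' @param selected character vector of selected genes (subset of universe).
#' @param terms named list: term -> character vector of member genes
#'   (intersected with the universe).
#' @param universe character vector, the gene population.
#' @return data.frame: term, overlap, term_size (K), n_selected, universe
#'   (N), p_value, fdr; sorted by p.
#' @export
hypergeom_enrich <- function(selected, terms, universe) {
  if (!length(universe)) stopf("empty universe")
  if (!length(selected)) stopf("empty selection")
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe)) stopf("selected genes must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(terms), function(tm) {
    term_genes <- intersect(unique(terms[[tm]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, selected))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, n_selected = n,
               universe = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
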