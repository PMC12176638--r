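UNANNOTATED <- "unannotated"

#' Principal-component embedding of cells
#'
#' Centered PCA of the normalized expression matrix (cells as
#' observations), keeping the leading components. Component signs are fixed
#' by convention: the largest-magnitude gene loading of each component is
#' made positive, so the embedding is deterministic.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param n_components number of components (default 50).
#' @return cells x n_components score matrix with an attribute
#'   \code{sdev} of component standard deviations.
#' @export
embed_pca <- function(expr, n_components = 50) {
  x <- t(expr$values)  # cells x genes
  if (nrow(x) < n_components)
    stopf("fewer cells (%d) than requested components (%d)", nrow(x), n_components)
  keep <- apply(x, 2, function(v) var(v) > 0)
  if (sum(keep) < n_components)
    stopf("only %d non-constant genes for %d components", sum(keep), n_components)
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- colnames(expr$values)
  attr(scores, "sdev") <- pc$sdev[seq_len(ncol(scores))]
  scores
}

## k-nearest-neighbour index matrix from an embedding (self excluded);
## O(n^2) distances — adequate at atlas scale (thousands of cells)
knn_index <- function(embedding, k) {
  d <- as.matrix(dist(embedding))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

## shared-nearest-neighbour graph with Jaccard edge weights, pruned at prune
snn_graph <- function(embedding, k = 15, prune = 1 / 15) {
  n <- nrow(embedding)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  nn <- knn_index(embedding, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  diag(adj) <- 1  # neighbourhood includes the cell itself, as is conventional
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(embedding)
  g
}

#' Cluster cells on a shared-nearest-neighbour graph
#'
#' Builds an SNN graph (k nearest neighbours, Jaccard edge weights, weak
#' edges pruned) over the embedding and partitions it by modularity-based
#' community detection at the given resolution. Fixed seed implies a fixed
#' partition.
#'
#' @param embedding cells x components matrix from \code{\link{embed_pca}}.
#' @param resolution modularity resolution parameter (> 0); larger values
#'   give more, smaller clusters.
#' @param k neighbours per cell (default 15).
#' @param seed integer seed for the community search.
#' @param label "low" or "high", recorded on the result.
#' @return object of class \code{cluster_assignment}: integer cluster ids
#'   (dense from 0) named by cell, \code{n_clusters}, \code{resolution},
#'   \code{label}.
#' @export
cluster_cells <- function(embedding, resolution, k = 15, seed = 1L, label = "low") {
  if (resolution <= 0) stopf("resolution must be positive")
  g <- snn_graph(embedding, k = k)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  ids <- as.integer(factor(igraph::membership(comm))) - 1L
  names(ids) <- rownames(embedding)
  structure(list(cluster = ids, n_clusters = length(unique(ids)),
                 resolution = resolution, label = label),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s, res %.3g): %d cells in %d clusters\n",
              x$label, x$resolution, length(x$cluster), x$n_clusters))
  invisible(x)
}

#' Choose low and high clustering resolutions
#'
#' Operationalizes the "reasonable cluster numbers" stopping rule of a
#' coarse-to-fine resolution sweep: the low resolution is the smallest
#' tested value yielding at least as many clusters as declared marker
#' types; the high resolution the smallest yielding at least
#' \code{high_factor} times that count.
#'
#' @param embedding cells x components matrix.
#' @param n_types number of declared cell types.
#' @param ladder increasing candidate resolutions.
#' @param high_factor multiplier for the high-resolution target (default 3).
#' @param k,seed passed to \code{\link{cluster_cells}}.
#' @return list with \code{res_low} and \code{res_high}.
#' @export
choose_resolutions <- function(embedding, n_types,
                               ladder = c(0.01, 0.02, 0.04, 0.08, 0.15, 0.25,
                                          0.5, 1, 2, 4, 8, 16, 32, 64),
                               high_factor = 3, k = 15, seed = 1L) {
  res_low <- NA_real_; res_high <- NA_real_
  for (r in ladder) {
    nc <- cluster_cells(embedding, r, k = k, seed = seed)$n_clusters
    if (is.na(res_low) && nc >= n_types) res_low <- r
    ## the high resolution must be a genuinely finer clustering
    if (!is.na(res_low) && is.na(res_high) && r > res_low &&
        nc >= high_factor * n_types) { res_high <- r; break }
  }
  if (is.na(res_low)) res_low <- ladder[length(ladder)]
  if (is.na(res_high)) res_high <- ladder[length(ladder)]
  list(res_low = res_low, res_high = res_high)
}

#' Label clusters by average marker z-scores
#'
#' For each gene, the mean normalized expression per cluster is z-scored
#' across clusters; each (cluster, type) pair is scored by the average z
#' over that type's markers; a cluster is labelled with the argmax type if
#' the best average z reaches \code{z_min}, otherwise "unannotated". Ties
#' are broken by marker count, then lexicographic type name, and flagged.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param clusters a \code{\link{cluster_assignment}} with >= 2 clusters.
#' @param markers named list: cell type -> marker gene ids. Markers missing
#'   from the matrix are reported and dropped.
#' @param z_min minimum average marker z to assign a label (default 0.5).
#' @return list: \code{labels} (cluster id -> type or "unannotated"),
#'   \code{scores} (clusters x types average-z matrix), \code{z} (gene x
#'   cluster z table), \code{ties} (cluster ids with tied argmax),
#'   \code{missing_markers}.
#' @export
score_clusters_by_markers <- function(expr, clusters, markers, z_min = 0.5) {
  if (!length(markers)) stopf("empty marker set")
  if (clusters$n_clusters < 2) stopf("need >= 2 clusters to z-score across clusters")
  missing <- lapply(markers, function(g) setdiff(g, rownames(expr$values)))
  if (any(lengths(missing) > 0))
    warnf("dropping %d marker(s) absent from the matrix", sum(lengths(missing)))
  markers <- lapply(markers, function(g) intersect(g, rownames(expr$values)))
  if (all(lengths(markers) == 0)) stopf("no markers present in the matrix")

  cl <- clusters$cluster[colnames(expr$values)]
  cl_ids <- sort(unique(cl))
  cmeans <- vapply(cl_ids, function(cid)
    rowMeans(expr$values[, cl == cid, drop = FALSE]), numeric(nrow(expr$values)))
  colnames(cmeans) <- as.character(cl_ids)
  mu <- rowMeans(cmeans)
  sdv <- row_sds(cmeans)
  z <- (cmeans - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  types <- names(markers)
  scores <- t(vapply(as.character(cl_ids), function(cid)
    vapply(types, function(ty)
      if (length(markers[[ty]])) mean(z[markers[[ty]], cid]) else -Inf,
      numeric(1)),
    numeric(length(types))))
  rownames(scores) <- as.character(cl_ids)

  ties <- character(0)
  labels <- vapply(as.character(cl_ids), function(cid) {
    s <- scores[cid, ]
    m <- max(s)
    if (m < z_min) return(UNANNOTATED)
    hits <- which(s >= m - 1e-12)
    if (length(hits) > 1) {
      ties <<- c(ties, cid)
      hits <- hits[order(-lengths(markers)[hits], types[hits])]
    }
    types[hits[1]]
  }, character(1))
  list(labels = labels, scores = scores, z = z, ties = ties,
       missing_markers = missing)
}

## expand cluster labels to per-cell labels
cells_from_clusters <- function(clusters, cluster_labels) {
  setNames(unname(cluster_labels[as.character(clusters$cluster)]),
           names(clusters$cluster))
}

#' Consensus of two clustering-based annotations
#'
#' A cell keeps its type iff the low- and high-resolution labels agree and
#' neither is "unannotated"; otherwise it is "unannotated" pending
#' correlation-based re-annotation.
#'
#' @param labels_low,labels_high named character vectors (cell -> type)
#'   covering the same cells.
#' @return object of class \code{consensus_labels}: \code{type} per cell,
#'   \code{source} ("consensus" or "unannotated"), \code{r} (NA at this
#'   stage), \code{stage} (NA until \code{\link{stage_annotate}}).
#' @export
consensus_annotation <- function(labels_low, labels_high) {
  if (!setequal(names(labels_low), names(labels_high)))
    stopf("label maps cover different cell sets")
  labels_high <- labels_high[names(labels_low)]
  agree <- labels_low == labels_high & labels_low != UNANNOTATED
  type <- ifelse(agree, labels_low, UNANNOTATED)
  structure(list(type = setNames(type, names(labels_low)),
                 source = setNames(ifelse(agree, "consensus", UNANNOTATED),
                                   names(labels_low)),
                 r = setNames(rep(NA_real_, length(type)), names(labels_low)),
                 stage = setNames(rep(NA_character_, length(type)), names(labels_low)),
                 tie = setNames(rep(FALSE, length(type)), names(labels_low))),
            class = "consensus_labels")
}

#' @export
print.consensus_labels <- function(x, ...) {
  cat(sprintf("consensus_labels: %d cells, %d annotated (%d by consensus, %d by correlation)\n",
              length(x$type), sum(x$type != UNANNOTATED),
              sum(x$source == "consensus"), sum(x$source == "correlation")))
  invisible(x)
}

#' Reference expression profiles from consensus cells
#'
#' Per-type arithmetic mean of normalized expression over the confidently
#' (consensus) annotated cells. Types with no consensus cell are dropped
#' with a warning.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param consensus a \code{\link{consensus_labels}}.
#' @return genes x types numeric matrix.
#' @export
build_reference_profiles <- function(expr, consensus) {
  type <- consensus$type[colnames(expr$values)]
  types <- sort(setdiff(unique(type), UNANNOTATED))
  if (!length(types)) stopf("no consensus-annotated cells: cannot build profiles")
  prof <- vapply(types, function(ty)
    rowMeans(expr$values[, type == ty, drop = FALSE]), numeric(nrow(expr$values)))
  rownames(prof) <- rownames(expr$values)
  prof
}

#' Correlation-based re-annotation of all cells
#'
#' Assigns every cell the type whose reference profile it correlates with
#' best (Pearson), storing the correlation. Constant-expression cells have
#' undefined correlation and stay "unannotated". Exact ties are broken
#' lexicographically and flagged.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param profiles genes x types matrix from
#'   \code{\link{build_reference_profiles}}.
#' @param genes optional gene subset on which to correlate (default: all
#'   shared genes). The pipeline wrapper uses the union of markers and the
#'   most variable genes.
#' @return a complete \code{\link{consensus_labels}} with source
#'   "correlation" (or "unannotated" for constant cells).
#' @export
correlation_annotate <- function(expr, profiles, genes = NULL) {
  if (ncol(profiles) < 2) stopf("need >= 2 reference profiles")
  if (!all(rownames(profiles) %in% rownames(expr$values)))
    stopf("profile gene set not contained in the expression matrix")
  genes <- genes %||% rownames(profiles)
  genes <- intersect(genes, rownames(profiles))
  if (length(genes) < 3) stopf("fewer than 3 genes shared for correlation")
  x <- expr$values[genes, , drop = FALSE]
  p <- profiles[genes, , drop = FALSE]
  const_cell <- apply(x, 2, function(v) var(v) == 0)
  const_prof <- apply(p, 2, function(v) var(v) == 0)
  if (any(const_prof)) stopf("constant reference profile(s): %s",
                             paste(colnames(p)[const_prof], collapse = ", "))
  r <- suppressWarnings(cor(x, p))  # cells x types
  types <- colnames(p)
  n <- ncol(x)
  type <- rep(UNANNOTATED, n); rbest <- rep(NA_real_, n); tie <- rep(FALSE, n)
  ok <- which(!const_cell)
  if (length(ok)) {
    rs <- r[ok, , drop = FALSE]
    for (ii in seq_along(ok)) {
      a <- argmax_lex(rs[ii, ], types)
      type[ok[ii]] <- types[a$index]
      rbest[ok[ii]] <- rs[ii, a$index]
      tie[ok[ii]] <- a$tie
    }
  }
  cells <- colnames(expr$values)
  structure(list(type = setNames(type, cells),
                 source = setNames(ifelse(const_cell, UNANNOTATED, "correlation"), cells),
                 r = setNames(rbest, cells),
                 stage = setNames(rep(NA_character_, n), cells),
                 tie = setNames(tie, cells)),
            class = "consensus_labels")
}

#' Developmental-stage assignment against bulk zone profiles
#'
#' Correlates each cell with bulk expression profiles of morphologically
#' defined developmental zones (meristem, elongation, maturation) and
#' assigns the argmax-correlation stage.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param zones genes x zones matrix (log scale), e.g. from
#'   \code{\link{generate_bulk_zones}} or measured bulk RNA-seq.
#' @return list: \code{stage} (named per cell), \code{r} (best correlation),
#'   \code{ties} (logical per cell).
#' @export
stage_annotate <- function(expr, zones) {
  if (ncol(zones) < 2) stopf("need >= 2 zone profiles")
  common <- intersect(rownames(expr$values), rownames(zones))
  if (length(common) < 3) stopf("gene sets of cells and zones do not overlap")
  if (!all(rownames(zones) %in% rownames(expr$values)))
    stopf("zone profile genes missing from the expression matrix")
  r <- suppressWarnings(cor(expr$values[common, , drop = FALSE],
                            zones[common, , drop = FALSE]))
  zn <- colnames(zones)
  stage <- character(nrow(r)); rbest <- numeric(nrow(r)); tie <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (all(is.na(r[i, ]))) { stage[i] <- NA_character_; rbest[i] <- NA_real_; next }
    a <- argmax_lex(r[i, ], zn)
    stage[i] <- zn[a$index]; rbest[i] <- r[i, a$index]; tie[i] <- a$tie
  }
  list(stage = setNames(stage, colnames(expr$values)),
       r = setNames(rbest, colnames(expr$values)),
       ties = setNames(tie, colnames(expr$values)))
}

#' Spearman similarity between per-sample pseudobulk profiles
#'
#' Rank correlation of per-sample gene sums, the sample-level concordance
#' check run before integrating datasets.
#'
#' @param counts a \code{\link{count_matrix}} with >= 2 samples.
#' @return symmetric samples x samples Spearman correlation matrix with
#'   unit diagonal.
#' @export
sample_similarity <- function(counts) {
  samples <- unique(counts$cell_meta$sample)
  if (length(samples) < 2) stopf("need >= 2 samples")
  sums <- vapply(samples, function(s)
    Matrix::rowSums(counts$counts[, counts$cell_meta$sample == s, drop = FALSE]),
    numeric(nrow(counts$counts)))
  cor(sums, method = "spearman")
}

#' Most variable genes of an expression matrix
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param n number of genes (default 2000).
#' @return character vector of gene ids ordered by decreasing variance.
#' @export
variable_genes <- function(expr, n = 2000) {
  v <- row_sds(expr$values)^2
  rownames(expr$values)[order(v, decreasing = TRUE)][seq_len(min(n, length(v)))]
}

#' Full dual-resolution consensus annotation pipeline
#'
#' Runs the complete annotation scheme: PCA embedding, SNN clustering at a
#' low and a high resolution, marker z-score labelling of both clusterings,
#' consensus of the two, reference profiles averaged over consensus cells,
#' and correlation-based annotation of the cells the consensus leaves
#' unannotated. The correlation is computed on the marker genes: validated
#' markers are type-specific and developmentally stable, whereas globally
#' variable genes carry the stage gradient, which misleads a type
#' correlation (see the methods vignette). Setting
#' \code{overturn_consensus = TRUE} instead re-annotates every cell by
#' correlation. Optionally assigns developmental stages against bulk zone
#' profiles.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param markers named list: cell type -> marker gene ids.
#' @param zones optional genes x zones bulk profile matrix for stage
#'   assignment.
#' @param n_components,k,seed,z_min tuning parameters (see the stage
#'   functions).
#' @param res_low,res_high clustering resolutions; chosen by
#'   \code{\link{choose_resolutions}} when NULL.
#' @param correlation_genes gene set for the correlation stage (default:
#'   the marker genes).
#' @param overturn_consensus if TRUE the correlation stage relabels all
#'   cells, including confident consensus cells (default FALSE).
#' @return a \code{\link{consensus_labels}} with attributes \code{consensus}
#'   (the pre-correlation labels), \code{profiles}, \code{clusters} and
#'   \code{resolutions}.
#' @export
annotate_cells <- function(expr, markers, zones = NULL, n_components = 50,
                           k = 15, seed = 1L, z_min = 0.5,
                           res_low = NULL, res_high = NULL,
                           correlation_genes = NULL,
                           overturn_consensus = FALSE) {
  emb <- embed_pca(expr, n_components = n_components)
  if (is.null(res_low) || is.null(res_high)) {
    rr <- choose_resolutions(emb, n_types = length(markers), k = k, seed = seed)
    res_low <- res_low %||% rr$res_low
    res_high <- res_high %||% rr$res_high
  }
  cl_low <- cluster_cells(emb, res_low, k = k, seed = seed, label = "low")
  cl_high <- cluster_cells(emb, res_high, k = k, seed = seed, label = "high")
  sc_low <- score_clusters_by_markers(expr, cl_low, markers, z_min = z_min)
  sc_high <- score_clusters_by_markers(expr, cl_high, markers, z_min = z_min)
  lab_low <- cells_from_clusters(cl_low, sc_low$labels)
  lab_high <- cells_from_clusters(cl_high, sc_high$labels)
  cons <- consensus_annotation(lab_low, lab_high)
  prof <- build_reference_profiles(expr, cons)
  gset <- correlation_genes %||%
    intersect(unlist(markers, use.names = FALSE), rownames(expr$values))
  final <- correlation_annotate(expr, prof, genes = gset)
  if (!overturn_consensus) {
    keep <- cons$source == "consensus"
    final$type[keep] <- cons$type[keep]
  }
  ## cells confirmed by both clusterings keep their consensus provenance
  keep <- cons$source == "consensus" & cons$type == final$type
  final$source[keep] <- "consensus"
  if (!is.null(zones)) {
    st <- stage_annotate(expr, zones)
    final$stage <- st$stage
  }
  attr(final, "consensus") <- cons
  attr(final, "profiles") <- prof
  attr(final, "clusters") <- list(low = cl_low, high = cl_high)
  attr(final, "resolutions") <- c(low = res_low, high = res_high)
  attr(final, "single_res_labels") <- list(low = lab_low, high = lab_high)
  final
}
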