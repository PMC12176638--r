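#' Count matrix container
#'
#' Bundles an integer gene-by-cell count matrix with per-cell metadata
#' (sample, condition, handling flag) and per-gene flags (mitochondrial,
#' chloroplast, protoplasting-induced). This is the raw substrate of the
#' pipeline; all QC and aggregation operate on it.
#'
#' @param counts genes x cells matrix (dense or \code{Matrix} sparse) of
#'   non-negative integer counts with unique dimnames.
#' @param cell_meta data.frame with one row per cell: columns \code{cell_id},
#'   \code{sample}, \code{condition}; optional logical \code{protoplasted}.
#' @param gene_meta data.frame with one row per gene: column \code{gene_id};
#'   optional logicals \code{is_mito}, \code{is_chloroplast},
#'   \code{is_protoplast_induced}.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, cell_meta, gene_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stopf("duplicate cell identifiers")
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) stopf("counts must be non-negative integers")
  if (!identical(cell_meta$cell_id, colnames(counts)))
    stopf("cell_meta$cell_id must match counts columns in order")
  if (!identical(gene_meta$gene_id, rownames(counts)))
    stopf("gene_meta$gene_id must match counts rows in order")
  for (fl in c("is_mito", "is_chloroplast", "is_protoplast_induced"))
    if (is.null(gene_meta[[fl]])) gene_meta[[fl]] <- FALSE
  if (is.null(cell_meta$protoplasted)) cell_meta$protoplasted <- TRUE
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells; %d samples, %d conditions\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample)),
              length(unique(x$cell_meta$condition))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## per-cell UMI totals, recomputed (never cached stale)
umi_totals <- function(cm) Matrix::colSums(cm$counts)

subset_cells <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$cell_meta[match(colnames(cm$counts)[keep], cm$cell_meta$cell_id), , drop = FALSE],
               cm$gene_meta)
}

subset_genes <- function(cm, keep) {
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$cell_meta,
               cm$gene_meta[match(rownames(cm$counts)[keep], cm$gene_meta$gene_id), , drop = FALSE])
}

#' Normalized expression container
#'
#' Genes x cells matrix of log-scale normalized expression plus a provenance
#' note recording the normalization applied.
#'
#' @param values genes x cells numeric matrix, finite, non-negative.
#' @param provenance character scalar describing the transformation.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, provenance = "unspecified") {
  if (any(!is.finite(values))) stopf("expression values must be finite")
  structure(list(values = values, provenance = provenance), class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), x$provenance))
  invisible(x)
}
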