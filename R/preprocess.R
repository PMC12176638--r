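#' Quality-control thresholds
#'
#' Houses the cell- and gene-level QC cutoffs: the 5 percent mitochondrial
#' expression threshold, the top-1-percent UMI trim, and the absolute log2
#' fold-change cutoff of the protoplasting-induced gene screen.
#'
#' @param mito_max maximum mitochondrial count fraction per cell (default 0.05).
#' @param top_umi_frac fraction of highest-UMI cells removed after the mito
#'   filter (default 0.01).
#' @param protoplast_abs_log2fc absolute log2FC at or above which a gene is
#'   called protoplasting-affected (default 2).
#' @return validated list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(mito_max = 0.05, top_umi_frac = 0.01,
                          protoplast_abs_log2fc = 2) {
  if (mito_max <= 0 || mito_max >= 1) stopf("mito_max must lie in (0, 1)")
  if (top_umi_frac < 0 || top_umi_frac >= 1) stopf("top_umi_frac must lie in [0, 1)")
  if (protoplast_abs_log2fc <= 0) stopf("protoplast_abs_log2fc must be positive")
  structure(list(mito_max = mito_max, top_umi_frac = top_umi_frac,
                 protoplast_abs_log2fc = protoplast_abs_log2fc),
            class = "qc_thresholds")
}

#' Cell quality filtering
#'
#' Removes cells whose mitochondrial count fraction exceeds
#' \code{mito_max}, then removes the top \code{ceiling(top_umi_frac * n)}
#' remaining cells by UMI total (the doublet/outlier trim applied after the
#' mitochondrial screen).
#'
#' @param counts a \code{\link{count_matrix}} with at least one gene flagged
#'   mitochondrial.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with the filtered \code{counts} and a \code{report}
#'   data.frame (cell_id, reason, value) of removed cells.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  if (!any(counts$gene_meta$is_mito)) stopf("no genes flagged mitochondrial")
  tot <- umi_totals(counts)
  mito <- Matrix::colSums(counts$counts[counts$gene_meta$is_mito, , drop = FALSE])
  frac <- ifelse(tot > 0, mito / tot, 0)
  drop_mito <- frac > thresholds$mito_max
  keep <- which(!drop_mito)
  n_top <- if (thresholds$top_umi_frac > 0) ceiling(thresholds$top_umi_frac * length(keep)) else 0L
  drop_top <- integer(0)
  if (n_top > 0 && length(keep) > 0) {
    ord <- keep[order(tot[keep], decreasing = TRUE)]
    drop_top <- ord[seq_len(min(n_top, length(ord)))]
  }
  report <- rbind(
    data.frame(cell_id = colnames(counts$counts)[drop_mito],
               reason = rep("mito_fraction", sum(drop_mito)),
               value = frac[drop_mito], stringsAsFactors = FALSE),
    data.frame(cell_id = colnames(counts$counts)[drop_top],
               reason = rep("top_umi", length(drop_top)),
               value = tot[drop_top], stringsAsFactors = FALSE))
  rownames(report) <- NULL
  survivors <- setdiff(seq_len(ncol(counts$counts)), c(which(drop_mito), drop_top))
  if (!length(survivors))
    stopf("all cells removed by QC (%d mito-fraction, %d top-UMI)",
          sum(drop_mito), length(drop_top))
  list(counts = subset_cells(counts, survivors), report = report)
}

#' Protoplasting-induced gene screen
#'
#' Flags genes whose expression differs between a protoplasted and a
#' control bulk profile by at least \code{protoplast_abs_log2fc} in absolute
#' log2 fold change (inclusive), computed on CPM with a symmetric
#' pseudocount.
#'
#' @param bulk_protoplast,bulk_control named numeric vectors of mean counts
#'   or CPM over an identical gene set.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param pseudocount added to both CPM values before the ratio (default
#'   0.5 CPM).
#' @return character vector of flagged gene ids, with the per-gene log2FC
#'   and the pseudocount as attributes.
#' @export
protoplast_gene_screen <- function(bulk_protoplast, bulk_control,
                                   thresholds = qc_thresholds(), pseudocount = 0.5) {
  if (is.null(names(bulk_protoplast)) || is.null(names(bulk_control)) ||
      !identical(sort(names(bulk_protoplast)), sort(names(bulk_control))))
    stopf("profiles must share an identical named gene set")
  bulk_control <- bulk_control[names(bulk_protoplast)]
  cpm <- function(x) x / sum(x) * 1e6
  a <- cpm(bulk_protoplast); b <- cpm(bulk_control)
  lfc <- log2((a + pseudocount) / (b + pseudocount))
  hits <- names(lfc)[abs(lfc) >= thresholds$protoplast_abs_log2fc]
  structure(hits, log2fc = lfc, pseudocount = pseudocount)
}

#' Exclude gene lists from a count matrix
#'
#' Drops the union of the mitochondrial, chloroplast and
#' protoplasting-affected gene lists before integration and differential
#' expression. Unknown identifiers are reported but not fatal; remaining
#' gene order is preserved.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param mito,chloroplast,protoplast character vectors of gene ids.
#' @return the reduced \code{count_matrix}.
#' @export
exclude_genes <- function(counts, mito = character(), chloroplast = character(),
                          protoplast = character()) {
  lists <- list(mito = mito, chloroplast = chloroplast, protoplast = protoplast)
  all_ids <- unique(unlist(lists, use.names = FALSE))
  unknown <- setdiff(all_ids, rownames(counts$counts))
  if (length(unknown))
    warnf("%d excluded identifier(s) not present in the matrix: %s",
          length(unknown), paste(head(unknown, 5), collapse = ", "))
  keep <- which(!rownames(counts$counts) %in% all_ids)
  if (!length(keep)) stopf("gene exclusion would empty the matrix")
  subset_genes(counts, keep)
}

#' Median-library log-normalization
#'
#' Scales each cell to the median UMI total and applies log1p. A simple
#' variance-stabilizing substitute for regression-based normalization: the
#' downstream annotation and DE stages only require relative expression on
#' a log scale.
#'
#' @param counts a \code{\link{count_matrix}}; every cell must have >= 1
#'   count.
#' @return an \code{\link{expression_matrix}} (genes x cells, log scale).
#' @export
normalize_counts <- function(counts) {
  tot <- umi_totals(counts)
  if (any(tot == 0))
    stopf("zero-count cell(s): %s",
          paste(head(colnames(counts$counts)[tot == 0], 5), collapse = ", "))
  target <- median(tot)
  scaled <- counts$counts %*% Matrix::Diagonal(x = target / tot)
  vals <- as.matrix(log1p(scaled))
  dimnames(vals) <- dimnames(counts$counts)
  expression_matrix(vals, provenance = sprintf(
    "median-library scaling (target %.0f UMI) + log1p", target))
}
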