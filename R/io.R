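#' Write a count matrix as a 10x-style triplet
#'
#' Writes matrix.mtx (Matrix Market integer, genes as rows), genes.tsv
#' (gene_id + flags) and barcodes.tsv (cell_id + sample, condition) into a
#' directory.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_tenx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$counts, file.path(dir, "matrix.mtx"))
  write.table(counts$gene_meta, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(counts$cell_meta, file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style triplet directory
#'
#' @param dir directory containing matrix.mtx, genes.tsv, barcodes.tsv as
#'   written by \code{\link{write_tenx}}.
#' @return a \code{\link{count_matrix}}.
#' @export
read_tenx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.table(file.path(dir, "genes.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  cells <- read.table(file.path(dir, "barcodes.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  count_matrix(m, cells, genes)
}

#' Read a marker table (type, gene TSV)
#'
#' @param path TSV with columns \code{cell_type} and \code{gene}.
#' @return named list: cell type -> character vector of marker genes.
#' @export
read_markers <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  split(tab$gene, tab$cell_type)
}

#' Write a marker list as TSV
#'
#' @param markers named list: cell type -> gene ids.
#' @param path output TSV path.
#' @export
write_markers <- function(markers, path) {
  tab <- data.frame(cell_type = rep(names(markers), lengths(markers)),
                    gene = unlist(markers, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-cell annotation labels as TSV
#'
#' @param labels a \code{\link{consensus_labels}}.
#' @param path output TSV (cell, type, stage, source, r).
#' @export
write_labels <- function(labels, path) {
  tab <- data.frame(cell = names(labels$type), type = unname(labels$type),
                    stage = unname(labels$stage), source = unname(labels$source),
                    r = unname(labels$r), stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a water-loss series as CSV
#'
#' The CSV has a commented metadata header (root_length_m, root_diameter_m,
#' total_water_g) followed by time_min, cumulative_loss_pct columns.
#'
#' @param series a \code{\link{water_loss_series}}.
#' @param path CSV path.
#' @export
write_waterloss_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# root_length_m=%g root_diameter_m=%g total_water_g=%g",
                     series$root_length, series$root_diameter, series$total_water), con)
  utils::write.csv(data.frame(time_min = series$times,
                              cumulative_loss_pct = series$cumulative_loss),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waterloss_csv
#' @export
read_waterloss_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- c(root_length_m = NA_real_, root_diameter_m = NA_real_, total_water_g = NA_real_)
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE+]+", hdr))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[parts[1]] <- as.numeric(parts[2])
    }
  }
  tab <- utils::read.csv(path, comment.char = "#")
  water_loss_series(tab$time_min, tab$cumulative_loss_pct,
                    root_length = meta[["root_length_m"]],
                    root_diameter = meta[["root_diameter_m"]],
                    total_water = meta[["total_water_g"]], strict = FALSE)
}

#' Read / write a phonon map as per-channel CSV grids
#'
#' @param map a \code{\link{phonon_map}}.
#' @param dfb_path,alpha_path CSV paths for the two channels.
#' @export
write_phonon_csv <- function(map, dfb_path, alpha_path) {
  write.table(map$dfb, dfb_path, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(map$alpha, alpha_path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dfb_path)
}

#' @rdname write_phonon_csv
#' @export
read_phonon_csv <- function(dfb_path, alpha_path) {
  phonon_map(as.matrix(read.table(dfb_path, sep = ",")),
             as.matrix(read.table(alpha_path, sep = ",")))
}
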