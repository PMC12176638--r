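## shared fixtures: everything is generated in code, no data files

## small atlas for fast unit tests
small_config <- function(seed = 3, ...) {
  atlas_config(n_genes = 400, n_cells = 600,
               cell_types = c("cortex", "endodermis", "xylem"),
               markers_per_type = 3, protoplast_genes = 10, seed = seed, ...)
}

## the default stated world of the acceptance criteria:
## 8 types, 4 stages, 2000 cells, 1500 genes, marker effect 2, 5 markers/type
default_config <- function(seed = 1) atlas_config(seed = seed)

## hand-built count_matrix from a dense matrix and minimal metadata
tiny_cm <- function(counts, sample = NULL, condition = NULL, mito = integer(0)) {
  ng <- nrow(counts); nc <- ncol(counts)
  rownames(counts) <- sprintf("g%02d", seq_len(ng))
  colnames(counts) <- sprintf("c%02d", seq_len(nc))
  count_matrix(counts,
               data.frame(cell_id = colnames(counts),
                          sample = sample %||% rep("s1", nc),
                          condition = condition %||% rep("gel", nc),
                          stringsAsFactors = FALSE),
               data.frame(gene_id = rownames(counts),
                          is_mito = seq_len(ng) %in% mito,
                          stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## direct pseudobulk_table builder for DE tests (bypasses single cells)
make_pb <- function(y, condition, cell_type = "typeA", n_cells = 100) {
  colnames(y) <- sprintf("s%d.%s", seq_len(ncol(y)), cell_type)
  rownames(y) <- rownames(y) %||% sprintf("g%04d", seq_len(nrow(y)))
  pairs <- data.frame(pair = colnames(y), sample = sprintf("s%d", seq_len(ncol(y))),
                      cell_type = cell_type, condition = condition,
                      n_cells = n_cells, small = n_cells < 10,
                      stringsAsFactors = FALSE)
  structure(list(counts = y, pairs = pairs), class = "pseudobulk_table")
}

## global-null pseudobulk simulation (3 vs 3 replicates by default)
sim_null_pb <- function(n_genes = 2000, n_per = 3, seed = 1) {
  set.seed(seed)
  base <- 2^rnorm(n_genes, 3, 1.5)
  phi <- 0.1 * rgamma(n_genes, 4, 4)
  lib <- exp(rnorm(2 * n_per, 0, 0.2))
  y <- vapply(seq_len(2 * n_per),
              function(j) rnbinom(n_genes, mu = base * lib[j], size = 1 / phi),
              numeric(n_genes))
  rownames(y) <- sprintf("g%04d", seq_len(n_genes))
  make_pb(y, condition = rep(c("a", "b"), each = n_per))
}

## power-simulation config: 10% planted DEGs at |log2FC| = lfc in 2 of 8 types
power_config <- function(seed = 11, n_genes = 2000, n_cells = 2400,
                         frac_deg = 0.10, lfc = 2) {
  cfg0 <- atlas_config(n_genes = n_genes, n_cells = n_cells, seed = seed)
  gt <- atlas_gene_table(cfg0)
  free <- gt$gene_id[is.na(gt$marker_for) & !gt$is_mito & !gt$is_chloroplast &
                       !gt$is_protoplast_induced & gt$base_log2 > 0]
  n_deg <- round(frac_deg * n_genes / 2)
  set.seed(seed + 1000)
  g1 <- sample(free, n_deg)
  g2 <- sample(setdiff(free, g1), n_deg)
  atlas_config(n_genes = n_genes, n_cells = n_cells, seed = seed,
               planted_degs = list("compacted_vs_noncompacted" = list(
                 exodermis = setNames(rep(c(lfc, -lfc), length.out = n_deg), g1),
                 endodermis = setNames(rep(c(lfc, -lfc), length.out = n_deg), g2))))
}

## mean silhouette width of a labelling on an embedding (brute force)
mean_silhouette <- function(embedding, labels) {
  d <- as.matrix(dist(embedding))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

## exact hypergeometric upper tail by pmf enumeration (independent oracle)
hyper_upper_oracle <- function(k, K, N, n) {
  kk <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
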