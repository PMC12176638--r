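#' Configuration for the synthetic root atlas generator
#'
#' Describes the stated world the generator samples from: K cell types laid
#' out along a developmental-stage gradient, type-restricted marker genes,
#' condition-specific planted DEGs, mitochondrial / chloroplast /
#' protoplasting-induced gene sets, per-sample library-size variation, NB
#' overdispersion and logistic dropout.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param cell_types character vector of type names (default: the eight
#'   major rice-root tissues resolved by the pipeline).
#' @param stages ordered developmental stages along the root axis.
#' @param markers_per_type number of marker genes planted per type.
#' @param marker_log2_effect log2 mean shift of a marker in its home type.
#' @param type_log2_sd s.d. of the random per-(gene, type) log2 offsets that
#'   make up each type's broad expression program. Cell identity in real
#'   tissue is a transcriptome-wide program of which validated markers are
#'   only the curated tip; without this term types would be separable only
#'   on the handful of marker genes, which no clustering of real data
#'   relies on.
#' @param stage_log2_sd s.d. of per-gene log2 slopes across the ordered
#'   stage index (the developmental gradient).
#' @param samples_per_condition biological replicates per growth condition.
#' @param conditions growth conditions.
#' @param planted_degs named list keyed \code{"condB_vs_condA"}; each element
#'   a named list (cell type -> named numeric vector gene -> log2FC) applied
#'   to cells of condition B.
#' @param allow_deg_markers allow planted DEGs on marker genes (default
#'   FALSE: the sets must be disjoint).
#' @param frac_mito,frac_chloroplast fractions of genes flagged organellar.
#' @param mito_high_cells fraction of cells with elevated mitochondrial
#'   expression (the low-quality class the QC filter must catch).
#' @param mito_high_log2 log2 elevation of mito genes in those cells.
#' @param protoplast_genes number of genes with a handling-induced shift.
#' @param protoplast_log2 log2 shift of those genes under protoplasting.
#' @param libsize_lognormal \code{c(mu, sigma)} of the per-cell log-normal
#'   library-size factor (natural-log scale, mean-1 baseline at mu = 0).
#' @param nb_dispersion mean per-gene NB overdispersion (phi; variance =
#'   mu + phi mu^2).
#' @param dropout_midpoint,dropout_slope logistic dropout on the gene's
#'   baseline log2 mean: keep probability
#'   plogis(slope * (log2(mean) - midpoint)), applied to the mean before
#'   sampling.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return validated list of class \code{atlas_config}.
#' @export
atlas_config <- function(n_genes = 1500, n_cells = 2000,
                         cell_types = c("atrichoblast", "trichoblast", "exodermis",
                                        "sclerenchyma", "cortex", "endodermis",
                                        "phloem", "xylem"),
                         stages = c("meristem", "elongation", "maturation1", "maturation2"),
                         markers_per_type = 5, marker_log2_effect = 2,
                         type_log2_sd = 0.4, stage_log2_sd = 0.5,
                         samples_per_condition = 3,
                         conditions = c("gel", "noncompacted", "compacted"),
                         planted_degs = list(), allow_deg_markers = FALSE,
                         frac_mito = 0.05, frac_chloroplast = 0.03,
                         mito_high_cells = 0.05, mito_high_log2 = 3,
                         protoplast_genes = 50, protoplast_log2 = 3,
                         libsize_lognormal = c(mu = 0, sigma = 0.35),
                         nb_dispersion = 0.3,
                         dropout_midpoint = -2, dropout_slope = 1,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              cell_types = cell_types, stages = stages,
              markers_per_type = as.integer(markers_per_type),
              marker_log2_effect = marker_log2_effect,
              type_log2_sd = type_log2_sd, stage_log2_sd = stage_log2_sd,
              samples_per_condition = as.integer(samples_per_condition),
              conditions = conditions, planted_degs = planted_degs,
              allow_deg_markers = isTRUE(allow_deg_markers),
              frac_mito = frac_mito, frac_chloroplast = frac_chloroplast,
              mito_high_cells = mito_high_cells, mito_high_log2 = mito_high_log2,
              protoplast_genes = as.integer(protoplast_genes),
              protoplast_log2 = protoplast_log2,
              libsize_lognormal = libsize_lognormal,
              nb_dispersion = nb_dispersion,
              dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
              seed = as.integer(seed))
  validate_atlas_config(cfg)
  structure(cfg, class = "atlas_config")
}

validate_atlas_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_cells < 1) stopf("n_genes and n_cells must be positive")
  if (length(cfg$cell_types) < 1 || anyDuplicated(cfg$cell_types))
    stopf("cell_types must be non-empty and unique")
  if (length(cfg$stages) < 1 || anyDuplicated(cfg$stages))
    stopf("stages must be non-empty, unique and ordered")
  for (fr in c("frac_mito", "frac_chloroplast", "mito_high_cells"))
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) stopf("%s must lie in [0, 1]", fr)
  if (cfg$markers_per_type < 0) stopf("markers_per_type must be non-negative")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be non-negative")
  if (cfg$samples_per_condition < 1) stopf("need at least one sample per condition")
  needed <- cfg$markers_per_type * length(cfg$cell_types) + cfg$protoplast_genes
  if (needed > cfg$n_genes)
    stopf("n_genes (%d) too small for %d marker + %d protoplast genes", cfg$n_genes,
          cfg$markers_per_type * length(cfg$cell_types), cfg$protoplast_genes)
  invisible(cfg)
}

## per-gene keep probability of the logistic dropout, from baseline log2 mean
dropout_keep <- function(cfg, base_log2) {
  plogis(cfg$dropout_slope * (base_log2 - cfg$dropout_midpoint))
}

## deterministic gene-level structure implied by a config (flags, markers,
## baseline means, stage slopes, dispersions) -- shared by generate_atlas
## and the noise-free profile generators so both describe the same world.
atlas_gene_model <- function(cfg) {
  set.seed(cfg$seed)
  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  n_mito <- round(cfg$frac_mito * cfg$n_genes)
  n_chl <- round(cfg$frac_chloroplast * cfg$n_genes)
  special <- sample(cfg$n_genes, n_mito + n_chl + cfg$protoplast_genes)
  is_mito <- seq_len(cfg$n_genes) %in% special[seq_len(n_mito)]
  is_chl <- seq_len(cfg$n_genes) %in% special[n_mito + seq_len(n_chl)]
  is_pp <- seq_len(cfg$n_genes) %in% special[n_mito + n_chl + seq_len(cfg$protoplast_genes)]

  marker_for <- rep(NA_character_, cfg$n_genes)
  free <- setdiff(seq_len(cfg$n_genes), special)
  for (ty in cfg$cell_types) {
    pick <- sample(free, cfg$markers_per_type)
    marker_for[pick] <- ty
    free <- setdiff(free, pick)
  }

  base_log2 <- rnorm(cfg$n_genes, 0, 1.2)
  ## organellar transcripts kept low so healthy cells sit well under the
  ## 5% mito threshold; mito-high cells push past it via mito_high_log2
  base_log2[is_mito | is_chl] <- base_log2[is_mito | is_chl] - 1.5
  ## broad type-identity programs: random log2 offset per (gene, type);
  ## markers carry only their dedicated home-type effect
  type_off <- matrix(rnorm(cfg$n_genes * length(cfg$cell_types), 0, cfg$type_log2_sd),
                     cfg$n_genes, length(cfg$cell_types),
                     dimnames = list(NULL, cfg$cell_types))
  type_off[!is.na(marker_for), ] <- 0
  stage_slope <- rnorm(cfg$n_genes, 0, cfg$stage_log2_sd)
  stage_slope[!is.na(marker_for)] <- 0  # markers are stage-stable by design
  dispersion <- cfg$nb_dispersion * stats::rgamma(cfg$n_genes, shape = 4, rate = 4)

  ## planted DEGs must be real genes, and disjoint from markers unless allowed
  for (pair in names(cfg$planted_degs)) for (ty in names(cfg$planted_degs[[pair]])) {
    gs <- names(cfg$planted_degs[[pair]][[ty]])
    bad <- setdiff(gs, gene_id)
    if (length(bad)) stopf("planted DEG gene(s) not in gene universe: %s", paste(bad, collapse = ", "))
    if (!cfg$allow_deg_markers && any(!is.na(marker_for[match(gs, gene_id)])))
      stopf("planted DEGs overlap marker genes in pair %s; set allow_deg_markers = TRUE to permit", pair)
  }

  list(gene_id = gene_id, is_mito = is_mito, is_chloroplast = is_chl,
       is_protoplast_induced = is_pp, marker_for = marker_for,
       base_log2 = base_log2, type_off = type_off, stage_slope = stage_slope,
       dispersion = dispersion, keep_prob = dropout_keep(cfg, base_log2))
}

## expected (dropout-thinned, library-size-1) count mean for one (type, stage,
## condition) combination; the generator and the bulk profiles both use this.
expected_mu <- function(cfg, gm, type, stage_index, condition) {
  s_centered <- stage_index - (length(cfg$stages) + 1) / 2
  l2 <- gm$base_log2 + gm$type_off[, type] + gm$stage_slope * s_centered
  l2[!is.na(gm$marker_for) & gm$marker_for == type] <-
    l2[!is.na(gm$marker_for) & gm$marker_for == type] + cfg$marker_log2_effect
  for (pair in names(cfg$planted_degs)) {
    cond_b <- strsplit(pair, "_vs_", fixed = TRUE)[[1]][1]
    if (identical(cond_b, condition) && type %in% names(cfg$planted_degs[[pair]])) {
      v <- cfg$planted_degs[[pair]][[type]]
      idx <- match(names(v), gm$gene_id)
      l2[idx] <- l2[idx] + unname(v)
    }
  }
  2^l2 * gm$keep_prob
}

#' Generate a synthetic single-cell root atlas with ground truth
#'
#' Draws an integer gene x cell count matrix whose statistical structure
#' mirrors droplet scRNA-seq of root protoplasts: negative-binomial counts
#' with per-gene dispersion, logistic dropout, log-normal library sizes,
#' type-restricted markers, a developmental-stage gradient, planted
#' condition-specific DEGs, and a subpopulation of mito-high (low-quality)
#' cells. Deterministic for a fixed config seed.
#'
#' @param config an \code{\link{atlas_config}}.
#' @return list with \code{counts} (a \code{\link{count_matrix}}) and
#'   \code{truth} (cell table, gene table, and the planted-DEG ledger).
#' @export
generate_atlas <- function(config) {
  validate_atlas_config(config)
  cfg <- config
  gm <- atlas_gene_model(cfg)  # seeds the RNG with cfg$seed

  n <- cfg$n_cells
  cell_id <- sprintf("cell%05d", seq_len(n))
  ## balanced assignment so every declared type/stage/sample is populated
  type <- sample(rep(cfg$cell_types, length.out = n))
  stage_idx <- sample(rep(seq_along(cfg$stages), length.out = n))
  cond <- rep(cfg$conditions, length.out = n)
  samp_within <- rep(seq_len(cfg$samples_per_condition),
                     length.out = n)[sample(n)]
  cond <- cond[sample(n)]
  sample_id <- paste0(cond, "_s", samp_within)
  if (any(tabulate(factor(type, cfg$cell_types)) == 0))
    stopf("zero cells drawn for type(s): %s",
          paste(cfg$cell_types[tabulate(factor(type, cfg$cell_types),
                                        length(cfg$cell_types)) == 0], collapse = ", "))
  is_mito_high <- runif(n) < cfg$mito_high_cells
  libfac <- exp(rnorm(n, cfg$libsize_lognormal[[1]], cfg$libsize_lognormal[[2]]))

  counts <- matrix(0L, cfg$n_genes, n, dimnames = list(gm$gene_id, cell_id))
  strata <- interaction(type, stage_idx, cond, drop = TRUE)
  size_g <- 1 / pmax(gm$dispersion, 1e-12)
  for (st in levels(strata)) {
    idx <- which(strata == st)
    mu0 <- expected_mu(cfg, gm, type[idx[1]], stage_idx[idx[1]], cond[idx[1]])
    mu <- outer(mu0, libfac[idx])
    hi <- is_mito_high[idx]
    if (any(hi)) mu[gm$is_mito, hi] <- mu[gm$is_mito, hi] * 2^cfg$mito_high_log2
    counts[, idx] <- rnbinom(length(mu), mu = mu, size = size_g)
  }

  cell_meta <- data.frame(cell_id = cell_id, sample = sample_id, condition = cond,
                          protoplasted = TRUE, stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = gm$gene_id, is_mito = gm$is_mito,
                          is_chloroplast = gm$is_chloroplast,
                          is_protoplast_induced = gm$is_protoplast_induced,
                          stringsAsFactors = FALSE)
  cm <- count_matrix(counts, cell_meta, gene_meta)

  planted <- do.call(rbind, c(list(data.frame(pair = character(), cell_type = character(),
                                              gene = character(), log2fc = numeric())),
    lapply(names(cfg$planted_degs), function(pair)
      do.call(rbind, lapply(names(cfg$planted_degs[[pair]]), function(ty)
        data.frame(pair = pair, cell_type = ty,
                   gene = names(cfg$planted_degs[[pair]][[ty]]),
                   log2fc = unname(cfg$planted_degs[[pair]][[ty]]),
                   stringsAsFactors = FALSE))))))
  truth <- list(
    cells = data.frame(cell_id = cell_id, true_type = type,
                       true_stage = cfg$stages[stage_idx], sample = sample_id,
                       condition = cond, is_mito_high = is_mito_high,
                       libsize_factor = libfac, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gm$gene_id, marker_for = gm$marker_for,
                       is_mito = gm$is_mito, is_chloroplast = gm$is_chloroplast,
                       is_protoplast_induced = gm$is_protoplast_induced,
                       base_log2 = gm$base_log2, stage_slope = gm$stage_slope,
                       dispersion = gm$dispersion, stringsAsFactors = FALSE),
    planted_degs = planted)
  list(counts = cm, truth = truth)
}

#' Gene-level structure implied by a config
#'
#' Deterministic gene table of the stated world (flags, marker assignments,
#' baseline abundances, stage slopes, dispersions) without sampling any
#' cells; useful for choosing genes on which to plant DEGs.
#'
#' @param config an \code{\link{atlas_config}}.
#' @return data.frame with one row per gene.
#' @export
atlas_gene_table <- function(config) {
  gm <- atlas_gene_model(config)
  data.frame(gene_id = gm$gene_id, marker_for = gm$marker_for,
             is_mito = gm$is_mito, is_chloroplast = gm$is_chloroplast,
             is_protoplast_induced = gm$is_protoplast_induced,
             base_log2 = gm$base_log2, stage_slope = gm$stage_slope,
             dispersion = gm$dispersion, keep_prob = gm$keep_prob,
             stringsAsFactors = FALSE)
}

#' Expected counts of the stated world
#'
#' The dropout-thinned expected count vector (at unit library-size factor)
#' for cells of one (type, stage, condition) stratum -- the exact means the
#' generator samples around, for moment-recovery checks and noise-free
#' profiles.
#'
#' @param config an \code{\link{atlas_config}}.
#' @param type cell type name.
#' @param stage stage name (default: middle of the gradient).
#' @param condition condition name (default first).
#' @return named numeric vector of expected counts per gene.
#' @export
atlas_expected_means <- function(config, type, stage = NULL,
                                 condition = config$conditions[1]) {
  gm <- atlas_gene_model(config)
  stage_index <- if (is.null(stage)) (length(config$stages) + 1) / 2
                 else match(stage, config$stages)
  if (is.na(stage_index)) stopf("unknown stage")
  if (!type %in% config$cell_types) stopf("unknown cell type: %s", type)
  setNames(expected_mu(config, gm, type, stage_index, condition), gm$gene_id)
}

#' Marker table implied by a config
#'
#' @param config an \code{\link{atlas_config}}.
#' @return named list: cell type -> character vector of marker gene ids
#'   (the role of a validated marker table).
#' @export
atlas_marker_set <- function(config) {
  gm <- atlas_gene_model(config)
  out <- lapply(config$cell_types, function(ty) gm$gene_id[!is.na(gm$marker_for) & gm$marker_for == ty])
  names(out) <- config$cell_types
  out
}

#' Noise-free bulk developmental-zone profiles
#'
#' One expression profile per declared stage, equal to the expected
#' normalized (log1p) expression of cells at that stage averaged over cell
#' types — the synthetic stand-in for bulk RNA-seq of morphologically
#' dissected meristem / elongation / maturation root sections.
#'
#' @param config an \code{\link{atlas_config}}.
#' @param per_type if TRUE return a profile per (type, stage) instead of
#'   averaging over types.
#' @param condition condition whose expectation is profiled (default first).
#' @return genes x zones numeric matrix (log1p scale).
#' @export
generate_bulk_zones <- function(config, per_type = FALSE, condition = config$conditions[1]) {
  gm <- atlas_gene_model(config)
  zones <- lapply(seq_along(config$stages), function(si) {
    per <- vapply(config$cell_types, function(ty) expected_mu(config, gm, ty, si, condition),
                  numeric(config$n_genes))
    if (per_type) per else rowMeans(per)
  })
  if (per_type) {
    out <- do.call(cbind, zones)
    colnames(out) <- as.vector(outer(config$cell_types, config$stages,
                                     function(t, s) paste(s, t, sep = ".")))
  } else {
    out <- vapply(zones, identity, numeric(config$n_genes))
    colnames(out) <- config$stages
  }
  rownames(out) <- gm$gene_id
  log1p(out)
}

#' Noise-free protoplasting control profiles
#'
#' Mean expression (CPM) of the stated world with and without the
#' protoplasting handling shift, the planted positive set for the
#' protoplasting-induced gene screen.
#'
#' @param config an \code{\link{atlas_config}}.
#' @return list with numeric vectors \code{control} and \code{protoplasted}
#'   (CPM scale) and the truth gene flags.
#' @export
generate_protoplast_profiles <- function(config) {
  gm <- atlas_gene_model(config)
  base <- rowMeans(vapply(config$cell_types, function(ty)
    expected_mu(config, gm, ty, (length(config$stages) + 1) / 2, config$conditions[1]),
    numeric(config$n_genes)))
  shifted <- base
  shifted[gm$is_protoplast_induced] <- shifted[gm$is_protoplast_induced] * 2^config$protoplast_log2
  cpm <- function(x) stats::setNames(x / sum(x) * 1e6, gm$gene_id)
  list(control = cpm(base), protoplasted = cpm(shifted),
       truth = gm$is_protoplast_induced)
}

#' Simulate a cumulative radial water-loss series
#'
#' Samples the two-phase exponential decay model at a regular time grid and
#' adds Gaussian noise, emulating gravimetric water-loss measurements of
#' excised root segments (loss expressed as percent of total water content).
#'
#' @param decay a \code{\link{decay_fit}} or plain list with fields
#'   \code{plateau}, \code{span_fast}, \code{span_slow}, \code{k_fast},
#'   \code{k_slow} (percent units; rates per minute).
#' @param n_points number of time points (>= 4).
#' @param dt sampling interval in minutes (> 0).
#' @param noise_sd s.d. of additive Gaussian noise, percentage points.
#' @param seed integer seed.
#' @param root_length,root_diameter,total_water segment geometry (m) and
#'   water content (g) carried as metadata.
#' @return a \code{\link{water_loss_series}}.
#' @export
generate_waterloss <- function(decay, n_points = 60, dt = 0.5, noise_sd = 1,
                               seed = 1L, root_length = 0.03,
                               root_diameter = 0.001, total_water = 0.05) {
  if (dt <= 0) stopf("dt must be positive")
  if (n_points < 4) stopf("need at least 4 time points")
  check_decay_params(decay)
  set.seed(seed)
  t <- (seq_len(n_points) - 1) * dt
  w0 <- decay$plateau + decay$span_fast + decay$span_slow
  loss <- w0 - two_phase_remaining(t, decay) + rnorm(n_points, 0, noise_sd)
  loss[1] <- max(loss[1], 0)
  water_loss_series(times = t, cumulative_loss = loss, root_length = root_length,
                    root_diameter = root_diameter, total_water = total_water,
                    strict = FALSE)
}

#' Simulate a two-component phonon-microscopy map
#'
#' Draws per-pixel (relative Brillouin frequency shift, acoustic
#' attenuation) pairs from a two-component bivariate Gaussian mixture with
#' known truth labels — the stand-in for a segmented endodermal region of
#' interest.
#'
#' @param means list of two length-2 mean vectors (dfb, alpha).
#' @param covs list of two 2x2 symmetric positive-definite covariances.
#' @param weights length-2 non-negative weights summing to 1.
#' @param grid c(rows, cols) of the pixel raster.
#' @param seed integer seed.
#' @return a \code{\link{phonon_map}} with per-pixel truth labels.
#' @export
generate_phonon_map <- function(means, covs, weights = c(0.5, 0.5),
                                grid = c(50, 50), seed = 1L) {
  if (length(weights) != 2 || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stopf("weights must be two non-negative values summing to 1")
  chols <- lapply(covs, function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stopf("covariance matrices must be symmetric positive definite")
    chol(S)
  })
  set.seed(seed)
  npx <- prod(grid)
  comp <- sample(1:2, npx, replace = TRUE, prob = weights)
  z <- matrix(rnorm(2 * npx), npx, 2)
  xy <- matrix(NA_real_, npx, 2)
  for (k in 1:2) {
    idx <- comp == k
    if (any(idx)) xy[idx, ] <- z[idx, , drop = FALSE] %*% chols[[k]] +
        matrix(means[[k]], sum(idx), 2, byrow = TRUE)
  }
  phonon_map(dfb = matrix(xy[, 1], grid[1], grid[2]),
             alpha = matrix(xy[, 2], grid[1], grid[2]),
             truth = matrix(comp, grid[1], grid[2]))
}
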