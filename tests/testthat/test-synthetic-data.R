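test_that("generate_atlas honours shape, determinism and config validation", {
  cfg <- atlas_config(n_genes = 500, n_cells = 300,
                      cell_types = c("A", "B", "C"), markers_per_type = 3,
                      protoplast_genes = 10, seed = 7)
  a1 <- generate_atlas(cfg)
  expect_identical(dim(a1$counts$counts), c(500L, 300L))
  expect_identical(nrow(a1$truth$cells), 300L)
  expect_setequal(a1$truth$cells$cell_id, colnames(a1$counts$counts))

  a2 <- generate_atlas(cfg)
  expect_identical(as.matrix(a1$counts$counts), as.matrix(a2$counts$counts))
  expect_identical(a1$truth, a2$truth)

  expect_error(atlas_config(n_genes = 20, markers_per_type = 5), "too small")
  expect_error(atlas_config(frac_mito = 1.5), "\\[0, 1\\]")
})

test_that("marker genes are elevated ~2^effect in their home type", {
  ## isolate the marker effect: no type programs, no gradient
  cfg <- atlas_config(n_genes = 400, n_cells = 3000, cell_types = c("A", "B", "C"),
                      markers_per_type = 3, marker_log2_effect = 2,
                      type_log2_sd = 0, stage_log2_sd = 0, mito_high_cells = 0,
                      protoplast_genes = 5, seed = 3)
  atlas <- generate_atlas(cfg)
  g <- atlas$truth$genes; cells <- atlas$truth$cells
  x <- as.matrix(atlas$counts$counts)
  idx <- which(!is.na(g$marker_for) & g$base_log2 >= 0)  # exclude near-zero-mean markers
  expect_gt(length(idx), 3)
  for (i in idx) {
    home <- cells$true_type == g$marker_for[i]
    ratio <- mean(x[i, home]) / mean(x[i, !home])
    expect_lt(abs(ratio - 4) / 4, 0.15)
  }
})

test_that("empirical moments match the stated NB law", {
  cfg <- atlas_config(n_genes = 500, n_cells = 6000, cell_types = "cortex",
                      stages = "meristem", markers_per_type = 2,
                      libsize_lognormal = c(mu = 0, sigma = 0),
                      mito_high_cells = 0, protoplast_genes = 10, seed = 5)
  atlas <- generate_atlas(cfg)
  mu <- atlas_expected_means(cfg, "cortex", "meristem")
  v <- mu + atlas$truth$genes$dispersion * mu^2
  x <- as.matrix(atlas$counts$counts)
  sel <- mu >= 1
  expect_true(all(abs(rowMeans(x)[sel] - mu[sel]) / mu[sel] < 0.10))
  expect_true(all(abs(apply(x, 1, var)[sel] - v[sel]) / v[sel] < 0.10))
})

test_that("bulk zone profiles reflect the stage structure", {
  cfg <- small_config()
  zones <- generate_bulk_zones(cfg)
  expect_identical(colnames(zones), cfg$stages)
  expect_true(all(is.finite(zones)) && all(zones >= 0))

  flat <- small_config(stage_log2_sd = 0)
  zflat <- generate_bulk_zones(flat)
  expect_equal(zflat[, 1], zflat[, 4], ignore_attr = TRUE)

  ## cells correlate best with their own stage's profile
  atlas <- generate_atlas(cfg)
  expr <- normalize_counts(atlas$counts)
  st <- stage_annotate(expr, zones[rownames(expr$values), ])
  acc <- mean(st$stage == atlas$truth$cells$true_stage[
    match(names(st$stage), atlas$truth$cells$cell_id)])
  expect_gte(acc, 0.90)
})

test_that("generate_waterloss is exact at zero noise and reproducible", {
  planted <- decay_fit(plateau = 20, span_fast = 50, span_slow = 30,
                       k_fast = 0.15, k_slow = 0.01)
  s0 <- generate_waterloss(planted, n_points = 20, dt = 1, noise_sd = 0, seed = 1)
  w0 <- planted$plateau + planted$span_fast + planted$span_slow
  t <- s0$times
  model_loss <- w0 - (planted$plateau + planted$span_fast * exp(-planted$k_fast * t) +
                        planted$span_slow * exp(-planted$k_slow * t))
  expect_equal(s0$cumulative_loss, model_loss)
  expect_equal(generate_waterloss(planted, 20, 1, 1, seed = 9)$cumulative_loss,
               generate_waterloss(planted, 20, 1, 1, seed = 9)$cumulative_loss)
  expect_error(generate_waterloss(planted, n_points = 3, dt = 1), "4 time points")
  expect_error(generate_waterloss(planted, n_points = 20, dt = -1), "positive")
})

test_that("generate_phonon_map respects weights, truth and PD checks", {
  m1 <- generate_phonon_map(means = list(c(0, 0), c(5, 5)),
                            covs = list(diag(2), diag(2)),
                            weights = c(1, 0), grid = c(10, 10), seed = 2)
  expect_true(all(m1$truth == 1))

  m2 <- generate_phonon_map(means = list(c(0, 0), c(5, 5)),
                            covs = list(diag(2), diag(2)),
                            weights = c(0.3, 0.7), grid = c(100, 100), seed = 2)
  frac <- mean(m2$truth == 1)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))  # binomial error

  expect_identical(generate_phonon_map(list(c(0,0), c(5,5)), list(diag(2), diag(2)),
                                       c(.5,.5), c(20, 20), seed = 4)$dfb,
                   generate_phonon_map(list(c(0,0), c(5,5)), list(diag(2), diag(2)),
                                       c(.5,.5), c(20, 20), seed = 4)$dfb)
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(generate_phonon_map(list(c(0,0), c(5,5)), list(bad, diag(2)),
                                   c(.5,.5), c(10, 10)), "positive definite")
})

test_that("planted DEGs are validated and recorded exactly", {
  cfg <- power_config(seed = 11, n_genes = 800, n_cells = 600, frac_deg = 0.05)
  atlas <- generate_atlas(cfg)
  pl <- atlas$truth$planted_degs
  spec <- cfg$planted_degs$compacted_vs_noncompacted
  expect_setequal(pl$gene[pl$cell_type == "exodermis"], names(spec$exodermis))
  expect_equal(pl$log2fc[match(names(spec$exodermis),
                               pl$gene[pl$cell_type == "exodermis"])],
               unname(spec$exodermis))
  ## markers and planted DEGs are disjoint unless explicitly allowed
  gt <- atlas_gene_table(cfg)
  mk <- gt$gene_id[!is.na(gt$marker_for)]
  expect_error(
    atlas_config(n_genes = 800, seed = 11,
                 planted_degs = list("compacted_vs_noncompacted" =
                   list(exodermis = setNames(2, mk[1])))) |> generate_atlas(),
    "overlap marker")
})

test_that("planted pseudobulk log2FC signs are recovered empirically", {
  cfg <- power_config(seed = 21, n_genes = 800, n_cells = 1200, frac_deg = 0.05)
  atlas <- generate_atlas(cfg)
  tr <- atlas$truth
  labels <- setNames(tr$cells$true_type, tr$cells$cell_id)
  pb <- aggregate_pseudobulk(atlas$counts, labels)
  for (ty in unique(tr$planted_degs$cell_type)) {
    sel <- pb$pairs$cell_type == ty
    cpm <- sweep(pb$counts[, sel, drop = FALSE], 2,
                 colSums(pb$counts[, sel, drop = FALSE]), "/") * 1e6
    cond <- pb$pairs$condition[sel]
    lfc <- log2((rowMeans(cpm[, cond == "compacted", drop = FALSE]) + 0.5) /
                  (rowMeans(cpm[, cond == "noncompacted", drop = FALSE]) + 0.5))
    pl <- tr$planted_degs[tr$planted_degs$cell_type == ty, ]
    expect_true(all(sign(lfc[pl$gene]) == sign(pl$log2fc)))
  }
})
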