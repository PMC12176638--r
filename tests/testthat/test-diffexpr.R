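test_that("aggregate_pseudobulk sums raw counts exactly and conserves totals", {
  counts <- matrix(c(1L, 2L, 3L, 4L, 7L, 1L), nrow = 2)
  cm <- tiny_cm(counts, sample = c("s1", "s1", "s2"),
                condition = c("gel", "gel", "gel"))
  labels <- c(c01 = "A", c02 = "A", c03 = "B")
  pb <- aggregate_pseudobulk(cm, labels)
  expect_equal(pb$counts[, "s1.A"], c(g01 = 4, g02 = 6))  # [1,2]+[3,4]
  expect_equal(pb$pairs$n_cells[pb$pairs$pair == "s1.A"], 2L)
  ## permutation invariance and conservation of annotated counts
  cmp <- tiny_cm(counts[, c(2, 3, 1)], sample = c("s1", "s2", "s1"))
  labp <- c(c01 = "A", c02 = "B", c03 = "A")
  expect_equal(aggregate_pseudobulk(cmp, labp)$counts[, "s1.A"],
               pb$counts[, "s1.A"])
  expect_equal(sum(pb$counts), sum(counts))
  ## unannotated cells excluded
  pb2 <- aggregate_pseudobulk(cm, c(c01 = "A", c02 = "unannotated", c03 = "B"))
  expect_equal(sum(pb2$counts), sum(counts[, -2]))
  expect_error(aggregate_pseudobulk(cm, c(c01 = "unannotated",
                                          c02 = "unannotated",
                                          c03 = "unannotated")), "no annotated")
})

test_that("nb_de_test: symmetry, planted effect recovery and error paths", {
  ## identical replicate tables in both conditions -> log2FC exactly 0
  set.seed(1)
  y1 <- matrix(rnbinom(300, mu = 20, size = 5), nrow = 100)
  pb <- make_pb(cbind(y1, y1), condition = rep(c("a", "b"), each = 3))
  tt <- nb_de_test(pb, "typeA", "a", "b")
  expect_true(all(abs(tt$log2fc) < 1e-9))

  ## planted 4-fold gene with large counts: log2FC = 2 +/- 0.2
  set.seed(2)
  base <- rep(200, 60)
  ya <- vapply(1:3, function(j) rnbinom(60, mu = base, size = 20), numeric(60))
  yb <- vapply(1:3, function(j) rnbinom(60, mu = base * c(4, rep(1, 59)), size = 20),
               numeric(60))
  rownames(ya) <- rownames(yb) <- sprintf("g%04d", 1:60)
  pb2 <- make_pb(cbind(ya, yb), condition = rep(c("a", "b"), each = 3))
  tt2 <- nb_de_test(pb2, "typeA", "a", "b")
  expect_lt(abs(tt2$log2fc[1] - 2), 0.2)
  expect_lt(tt2$p_value[1], 1e-4)

  ## a condition with < 2 usable pairs errors by name
  pb3 <- make_pb(cbind(ya[, 1, drop = FALSE], yb), condition = c("a", "b", "b", "b"))
  expect_error(nb_de_test(pb3, "typeA", "a", "b"), "condition a")
  ## pairs under min_cells are excluded
  pb4 <- make_pb(cbind(ya, yb), condition = rep(c("a", "b"), each = 3),
                 n_cells = c(100, 5, 5, 100, 100, 100))
  expect_error(nb_de_test(pb4, "typeA", "a", "b"), "condition a")
})

test_that("nb_de_test p-values are calibrated under the global null", {
  tt <- nb_de_test(sim_null_pb(n_genes = 2000, seed = 42), "typeA", "a", "b")
  ks <- suppressWarnings(stats::ks.test(tt$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  fdr <- p.adjust(tt$p_value, "BH")
  expect_lte(mean(fdr <= 0.05), 0.01)
})

test_that("detection_frequency matches a brute-force recount", {
  cfg <- small_config(seed = 14)
  atlas <- generate_atlas(cfg)
  cm <- atlas$counts
  labels <- setNames(atlas$truth$cells$true_type, atlas$truth$cells$cell_id)
  x <- as.matrix(cm$counts)
  set.seed(3)
  for (i in 1:20) {
    g <- sample(rownames(x), 1)
    ty <- sample(unique(labels), 1)
    cond <- sample(unique(cm$cell_meta$condition), 1)
    sel <- labels[colnames(x)] == ty & cm$cell_meta$condition == cond
    manual <- sum(x[g, sel] > 0) / sum(sel)  # explicit recount
    expect_equal(detection_frequency(cm, labels, g, ty, cond), manual)
  }
  expect_equal(detection_frequency(cm, labels, rownames(x)[1], labels[1],
                                   cm$cell_meta$condition[1]) >= 0, TRUE)
  expect_error(detection_frequency(cm, labels, "g", "no_such_type", "gel"),
               "empty stratum")
})

test_that("filter_degs applies inclusive rules, is order-invariant and monotone", {
  res <- data.frame(
    gene = sprintf("g%d", 1:6), cell_type = "A",
    log2fc = c(1, log2(1.5), 0.2, 3, -log2(1.5), 1),
    p_value = 1:6 / 100,
    fdr = c(0.01, 0.05, 0.01, 0.2, 0.05, 0.01),
    det_a = c(0.5, 0.10, 0.5, 0.5, 0.09, 0.09),
    det_b = c(0.4, 0.09, 0.4, 0.4, 0.10, 0.05))
  out <- filter_degs(res)
  ## g1 passes all; g2 is the exact boundary (fdr=0.05, FC=1.5, det=0.10): passes
  ## g3 fails FC; g4 fails fdr; g5 boundary passes (negative FC); g6 fails det
  expect_setequal(out$gene, c("g1", "g2", "g5"))
  ## gene-order invariance
  expect_setequal(filter_degs(res[sample(6), ])$gene, out$gene)
  ## monotone: loosening thresholds never removes a DEG
  loose <- filter_degs(res, de_thresholds(fdr_max = 0.3, fc_min = 1.1, det_min = 0.01))
  expect_true(all(out$gene %in% loose$gene))
})

test_that("deg_summary counts types and single-type genes correctly", {
  empty <- deg_summary(data.frame(gene = character(), cell_type = character()))
  expect_true(is.na(empty$unique_fraction))
  tab <- data.frame(gene = c("g1", "g1", "g2"), cell_type = c("A", "B", "A"))
  s <- deg_summary(tab)
  expect_equal(s$unique_fraction, 0.5)  # g2 unique, g1 shared
  ## against an independent tally
  cfg <- power_config(seed = 31, n_genes = 600, n_cells = 900, frac_deg = 0.05)
  atlas <- generate_atlas(cfg)
  labels <- setNames(atlas$truth$cells$true_type, atlas$truth$cells$cell_id)
  degs <- filter_degs(de_analysis(atlas$counts, labels, "noncompacted", "compacted"))
  s2 <- deg_summary(degs)
  manual <- table(degs$cell_type)
  expect_equal(as.integer(s2$counts[names(manual)]), as.integer(manual))
  expect_equal(s2$unique_fraction,
               mean(tapply(degs$cell_type, degs$gene,
                           function(v) length(unique(v))) == 1))
})

test_that("hypergeom_enrich matches exhaustive enumeration for N <= 20", {
  set.seed(6)
  for (rep in 1:30) {
    N <- sample(5:20, 1)
    universe <- sprintf("u%02d", 1:N)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    selected <- sample(universe, n)
    term <- list(t1 = sample(universe, K))
    out <- hypergeom_enrich(selected, term, universe)
    k <- length(intersect(term$t1, selected))
    expect_equal(out$p_value, hyper_upper_oracle(k, K, N, n), tolerance = 1e-12)
  }
  ## closed forms: total containment and disjoint term
  universe <- sprintf("u%03d", 1:100)
  sel <- universe[1:10]
  out1 <- hypergeom_enrich(sel, list(t = sel), universe)
  expect_equal(out1$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  out0 <- hypergeom_enrich(sel, list(t = universe[90:100]), universe)
  expect_lt(abs(out0$p_value - 1), 1e-12)
  expect_error(hypergeom_enrich(character(), list(t = sel), universe), "empty")
  expect_error(hypergeom_enrich("zz", list(t = sel), universe), "subset")
})

test_that("de_analysis end-to-end respects the detection filter by construction", {
  cfg <- power_config(seed = 41, n_genes = 600, n_cells = 900, frac_deg = 0.05)
  atlas <- generate_atlas(cfg)
  labels <- setNames(atlas$truth$cells$true_type, atlas$truth$cells$cell_id)
  res <- de_analysis(atlas$counts, labels, "noncompacted", "compacted")
  degs <- filter_degs(res)
  expect_true(all(pmax(degs$det_a, degs$det_b) >= 0.10))
  expect_true(all(degs$fdr >= degs$p_value))
  expect_true(all(res$det_a >= 0 & res$det_a <= 1 & res$det_b >= 0 & res$det_b <= 1))
})
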