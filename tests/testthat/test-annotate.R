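## shared small annotated world for several blocks
ann_cfg <- small_config(seed = 12)
ann_atlas <- generate_atlas(ann_cfg)
ann_expr <- normalize_counts(ann_atlas$counts)

test_that("embed_pca is a centered projection with fixed signs", {
  expr <- ann_expr
  emb <- embed_pca(expr, n_components = 20)
  expect_identical(dim(emb), c(ncol(expr$values), 20L))
  ## projection cannot create variance
  expect_lte(sum(apply(emb, 2, var)), sum(apply(t(expr$values), 2, var)) + 1e-8)
  ## rank-2 input: components beyond 2 carry ~zero variance
  u <- matrix(rnorm(60), 30); v <- matrix(rnorm(10), 2)
  low <- expression_matrix(t(u[, 1:2] %*% v) + 5)
  emb2 <- embed_pca(low, n_components = 5)
  expect_lt(sum(apply(emb2[, 3:5], 2, var)), 1e-20 * sum(apply(emb2, 2, var)))
  expect_error(embed_pca(expr, n_components = 1e4), "fewer cells")

  ## types are linearly separated: silhouette on truth beats shuffled labels
  truth <- ann_atlas$truth$cells$true_type
  set.seed(1)
  expect_gt(mean_silhouette(emb[1:300, ], truth[1:300]),
            mean_silhouette(emb[1:300, ], sample(truth[1:300])))
})

test_that("cluster_cells finds planted blobs and respects resolution ordering", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(300, 0), ncol = 2), matrix(rnorm(300, 8), ncol = 2))
  rownames(blob) <- sprintf("p%03d", 1:300)
  cl <- cluster_cells(blob, resolution = 0.1, k = 15, seed = 1)
  expect_equal(cl$n_clusters, 2)
  expect_equal(adjusted_rand_index(cl$cluster, rep(1:2, each = 150)), 1)

  ## duplicated point co-clusters with its twin
  dup <- rbind(blob, p301 = blob[1, ])
  cld <- cluster_cells(dup, resolution = 0.1, k = 15, seed = 1)
  expect_equal(unname(cld$cluster["p301"]), unname(cld$cluster["p001"]))

  ## monotone cluster counts along a resolution sweep
  emb <- embed_pca(ann_expr, 20)
  ncl <- vapply(c(0.25, 1, 4, 16), function(r)
    cluster_cells(emb, r, seed = 1)$n_clusters, numeric(1))
  expect_true(all(diff(ncl) >= 0))
  expect_error(cluster_cells(blob, 0.5, k = 400), "smaller than")
})

test_that("score_clusters_by_markers labels planted clusters and centers z", {
  expr <- ann_expr
  truth <- setNames(ann_atlas$truth$cells$true_type, ann_atlas$truth$cells$cell_id)
  markers <- atlas_marker_set(ann_cfg)
  ## clusters = truth labels (ideal clustering isolates the scorer)
  cl <- structure(list(cluster = setNames(as.integer(factor(truth)) - 1L, names(truth)),
                       n_clusters = length(unique(truth)),
                       resolution = 1, label = "low"),
                  class = "cluster_assignment")
  sc <- score_clusters_by_markers(expr, cl, markers, z_min = 0.5)
  lab <- sc$labels[as.character(cl$cluster)]
  expect_equal(unname(lab), unname(truth[names(cl$cluster)]))
  ## z rows sum to ~0 across clusters (centering identity)
  expect_lt(max(abs(rowSums(sc$z))), 1e-9)

  ## degenerate: identical expression in all clusters -> all unannotated
  flat <- expression_matrix(matrix(3, nrow(expr$values), 10,
                                   dimnames = list(rownames(expr$values),
                                                   sprintf("c%02d", 1:10))))
  clf <- structure(list(cluster = setNames(rep(0:1, 5), colnames(flat$values)),
                        n_clusters = 2, resolution = 1, label = "low"),
                   class = "cluster_assignment")
  scf <- score_clusters_by_markers(flat, clf, markers, z_min = 0.5)
  expect_true(all(scf$labels == "unannotated"))
  expect_error(score_clusters_by_markers(expr, cl, list()), "empty marker")
})

test_that("consensus_annotation applies the agreement rule", {
  low <- c(a = "A", b = "A", c = "B")
  high <- c(a = "A", b = "B", c = "B")
  cons <- consensus_annotation(low, high)
  expect_equal(unname(cons$type), c("A", "unannotated", "B"))
  cons2 <- consensus_annotation(low, low)
  expect_true(all(cons2$source == "consensus"))
  expect_error(consensus_annotation(low, high[1:2]), "different cell sets")
  ## "unannotated" agreeing with itself stays unannotated
  u <- c(a = "unannotated"); expect_equal(unname(consensus_annotation(u, u)$type),
                                          "unannotated")
})

test_that("reference profiles average consensus cells and rank correctly", {
  expr <- ann_expr
  truth <- setNames(ann_atlas$truth$cells$true_type, ann_atlas$truth$cells$cell_id)
  cons <- consensus_annotation(truth, truth)
  prof <- build_reference_profiles(expr, cons)
  expect_identical(colnames(prof), sort(unique(truth)))
  ## single-cell type: profile equals the cell
  one <- truth; one[one == "cortex"] <- "unannotated"
  one[names(one)[1]] <- "cortex"
  p1 <- build_reference_profiles(expr, consensus_annotation(one, one))
  expect_equal(p1[, "cortex"], expr$values[, names(one)[1]], ignore_attr = TRUE)
  ## permutation invariance
  set.seed(2)
  perm <- sample(ncol(expr$values))
  exprp <- expression_matrix(expr$values[, perm])
  expect_equal(build_reference_profiles(exprp, cons), prof)
  ## each profile correlates best with its own type's planted mean
  for (ty in colnames(prof)) {
    mu <- log1p(atlas_expected_means(ann_cfg, ty))
    r <- cor(mu[rownames(prof)], prof)
    expect_equal(colnames(prof)[which.max(r)], ty)
  }
})

test_that("correlation_annotate assigns argmax r with deterministic ties", {
  prof <- cbind(A = c(1, 2, 3, 4), B = c(2, 1, 4, 3))
  rownames(prof) <- sprintf("g%02d", 1:4)
  ## c3 is the average of both profiles: equal r to A and B by symmetry
  x <- cbind(c1 = prof[, "A"], c2 = c(2.5, 2.5, 2.5, 2.5),
             c3 = (prof[, "A"] + prof[, "B"]) / 2)
  ex <- expression_matrix(x)
  out <- correlation_annotate(ex, prof)
  expect_equal(unname(out$type["c1"]), "A")
  expect_equal(unname(out$r["c1"]), 1)
  expect_equal(unname(out$type["c2"]), "unannotated")  # constant cell
  ## c3 equidistant: equal r to both -> lexicographic tie-break, flagged
  expect_equal(unname(out$type["c3"]), "A")
  expect_true(out$tie[["c3"]])
  ## unannotated fraction reduces to the constant-cell fraction exactly
  expect_equal(sum(out$type == "unannotated"), 1)
  expect_error(correlation_annotate(ex, prof[, 1, drop = FALSE]), ">= 2")
})

test_that("stage_annotate assigns by zone correlation and flags degenerate ties", {
  zones <- generate_bulk_zones(ann_cfg)
  expr <- ann_expr
  st <- stage_annotate(expr, zones[rownames(expr$values), ])
  ## cell equal to a profile gets that stage
  exz <- expression_matrix(cbind(z1 = zones[rownames(expr$values), "meristem"]))
  expect_equal(unname(stage_annotate(exz, zones[rownames(expr$values), ])$stage), "meristem")
  ## identical profiles -> all tied
  zsame <- zones[rownames(expr$values), c(1, 1)]
  colnames(zsame) <- c("z1", "z2")
  expect_true(all(stage_annotate(expr, zsame)$ties))
  expect_error(stage_annotate(expr, zones[, 1, drop = FALSE]), ">= 2")
})

test_that("sample_similarity is a symmetric unit-diagonal Spearman matrix", {
  atlas <- ann_atlas
  s <- sample_similarity(atlas$counts)
  expect_equal(s, t(s), tolerance = 1e-12)
  expect_equal(unname(diag(s)), rep(1, nrow(s)))
  ## a sample duplicated gene-for-gene gives off-diagonal 1
  cm <- atlas$counts
  src <- cm$cell_meta$sample[1]
  idx <- which(cm$cell_meta$sample == src)
  dup <- cm$counts[, idx, drop = FALSE]
  colnames(dup) <- paste0("dup", seq_along(idx))
  meta_dup <- cm$cell_meta[idx, ]
  meta_dup$cell_id <- colnames(dup)
  meta_dup$sample <- "dupS"
  cm2 <- count_matrix(cbind(cm$counts, dup), rbind(cm$cell_meta, meta_dup),
                      cm$gene_meta)
  s2 <- sample_similarity(cm2)
  expect_equal(s2[src, "dupS"], 1)
})

test_that("the full pipeline recovers the planted annotation", {
  cfg <- small_config(seed = 12)
  labs <- annotate_cells(ann_expr, atlas_marker_set(cfg),
                         zones = generate_bulk_zones(cfg)[rownames(ann_expr$values), ],
                         n_components = 30, seed = 1)
  truth <- ann_atlas$truth$cells
  tt <- truth$true_type[match(names(labs$type), truth$cell_id)]
  expect_gte(mean(labs$type == tt), 0.95)
  expect_gte(adjusted_rand_index(labs$type, tt), 0.9)
  ## consensus subset at least as accurate as either single resolution
  cons <- attr(labs, "consensus")
  sl <- attr(labs, "single_res_labels")
  acc <- function(v) {
    s <- v != "unannotated"
    mean(v[s] == tt[s])
  }
  expect_gte(acc(cons$type) + 1e-12, max(acc(sl$low), acc(sl$high)))
})
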