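small_sc <- function(seed = 1, ...) {
  simulate_singlecell(sim_config(
    n_core_up = 0, n_core_down = 0, n_tfr_shared = 0,
    n_specific_per_condition = 0,
    n_genes = 600, n_clusters = 3, n_cells_per_cluster = 120,
    n_markers_per_cluster = 60, n_donors = 3, cell_library_mean = 1500,
    seed = seed, ...))
}

test_that("QC removes high-mito and low-count cells by the stated rules", {
  cells <- matrix(10L, 6, 5,
                  dimnames = list(paste0("c", 1:6),
                                  c("mt-a", paste0("g", 1:4))))
  # mito fractions: 0.25, 0.19, 0.20 exactly, rest low
  cells[1, ] <- c(15L, 12L, 11L, 11L, 11L)   # 15/60 = 0.25
  cells[2, ] <- c(19L, 20L, 20L, 20L, 21L)   # 19/100 = 0.19
  cells[3, ] <- c(20L, 20L, 20L, 20L, 20L)   # 20/100 = 0.20
  out <- qc_filter_cells(cells, mito_max = 0.20, count_quantile = NULL)
  expect_false("c1" %in% rownames(out))  # above
  expect_true("c2" %in% rownames(out))   # below
  expect_false("c3" %in% rownames(out))  # inclusive boundary removed

  # identical totals: strict '<' removes nobody
  even <- matrix(5L, 4, 4, dimnames = list(paste0("c", 1:4),
                                           c("mt-a", paste0("g", 1:3))))
  expect_identical(nrow(qc_filter_cells(even, mito_max = NULL,
                                        count_quantile = 0.10)), 4L)

  # 10 cells with totals 1..10: the type-7 10th percentile is 1.9, so only
  # the total-1 cell falls strictly below
  ladder <- matrix(0L, 10, 3, dimnames = list(paste0("c", 1:10),
                                              paste0("g", 1:3)))
  for (i in 1:10) ladder[i, 1] <- as.integer(i)
  out2 <- qc_filter_cells(ladder, mito_max = NULL, count_quantile = 0.10)
  expect_identical(rownames(out2), paste0("c", 2:10))

  expect_error(qc_filter_cells(ladder, mito_max = 0.2, count_quantile = NULL),
               "no gene matches")
})

test_that("log-normalization is scale-invariant per cell and matches the median rule", {
  cells <- rbind(c1 = c(10L, 30L, 60L), c2 = c(20L, 60L, 120L),
                 c3 = c(5L, 10L, 35L))
  colnames(cells) <- paste0("g", 1:3)
  norm <- lognormalize_cells(cells)
  # c2 = 2 * c1: identical normalized profiles
  expect_equal(norm["c1", ], norm["c2", ], tolerance = 1e-12)
  # hand check: totals (100, 200, 50), median 100 -> size factors (1, 2, 0.5)
  expect_equal(unname(attr(norm, "size_factors")), c(1, 2, 0.5))
  expect_equal(unname(norm["c3", 1]), log2(5 / 0.5 + 1))
  # all-equal cells: values are log2(count + 1)
  same <- rbind(c1 = c(4L, 8L), c2 = c(4L, 8L))
  colnames(same) <- c("g1", "g2")
  expect_equal(unname(lognormalize_cells(same)[1, ]), log2(c(4, 8) + 1))
  zero <- rbind(c1 = c(0L, 0L)); colnames(zero) <- c("g1", "g2")
  expect_error(lognormalize_cells(zero), "zero-total")
})

test_that("HVG selection ranks by variance with deterministic ties", {
  m <- cbind(flat = rep(1, 6), wild = c(0, 9, 1, 8, 2, 7),
             mid = c(1, 2, 1, 2, 1, 2), tie_a = c(0, 2, 0, 2, 0, 2),
             tie_b = c(2, 0, 2, 0, 2, 0))
  rownames(m) <- paste0("c", 1:6)
  hv <- select_hvgs(m, 3)
  expect_identical(hv[1], "wild")
  expect_false("flat" %in% select_hvgs(m, 4))
  expect_identical(select_hvgs(m, 10), select_hvgs(m, 5))
  # tie between tie_a and tie_b broken by id
  expect_identical(select_hvgs(m, 3)[2:3], c("tie_a", "tie_b"))
})

test_that("PCA separates planted blobs and is reproducible", {
  set.seed(30)
  blob <- rbind(matrix(rnorm(50 * 20, 0), 50, 20),
                matrix(rnorm(50 * 20, 3), 50, 20))
  dimnames(blob) <- list(paste0("c", 1:100), paste0("g", 1:20))
  emb <- pca_cells(blob, n_components = 5)
  expect_identical(emb, pca_cells(blob, n_components = 5))
  pc1 <- emb[, 1]
  expect_true(max(pc1[1:50]) < min(pc1[51:100]) ||
              min(pc1[1:50]) > max(pc1[51:100]))
  # duplicated cells share coordinates
  dup <- rbind(blob, blob[1, , drop = FALSE])
  rownames(dup)[101] <- "copy"
  e2 <- pca_cells(dup, n_components = 3)
  expect_equal(e2["c1", ], e2["copy", ], tolerance = 1e-9)
  # rank-1 data: first component captures essentially all variance
  r1 <- outer(1:30, seq(0.1, 2, length.out = 10))
  dimnames(r1) <- list(paste0("c", 1:30), paste0("g", 1:10))
  vf <- attr(pca_cells(r1, n_components = 2), "variance_fraction")
  expect_gt(vf[1], 0.999)
})

test_that("the kNN-Jaccard graph matches hand expectations", {
  # two far blobs with small k: no cross-blob edges
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 50, 0.1), 10, 2))
  rownames(pts) <- paste0("p", 1:20)
  g <- knn_jaccard_graph(pts, k = 3)
  ends <- igraph::as_edgelist(g)
  blob_of <- function(id) as.integer(sub("p", "", id)) > 10
  expect_true(all(blob_of(ends[, 1]) == blob_of(ends[, 2])))
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))

  # hand case: 4 collinear points; N(A)={B,C}, N(B)={A,C} at k=2
  line <- cbind(c(0, 1, 2.1, 10), 0)
  rownames(line) <- c("A", "B", "C", "D")
  g2 <- knn_jaccard_graph(line, k = 2)
  eid <- igraph::get_edge_ids(g2, c("A", "B"))
  expect_equal(igraph::E(g2)$weight[eid], 1 / 3)  # |{C}| / |{A,B,C}|
  expect_error(knn_jaccard_graph(line, k = 4), "smaller")
})

test_that("Louvain recovers disconnected cliques exactly and is seeded", {
  full5 <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(full5, full5)
  igraph::V(g)$name <- paste0("v", 1:10)
  igraph::E(g)$weight <- 1
  cl <- louvain_communities(g, seed = 5)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[1:5])), 1L)
  expect_identical(length(unique(cl[6:10])), 1L)
  expect_identical(cl, louvain_communities(g, seed = 5))
})

test_that("the full clustering pass recovers planted clusters (ARI >= 0.9)", {
  sim <- small_sc(seed = 11)
  # resolution 0.3: coarse setting for desk-scale data (hundreds of cells,
  # a handful of populations); the default 1.0 resolves finer substructure
  res <- cluster_cells(sim$cells, n_hvgs = 300, n_components = 10, k = 9,
                       resolution = 0.3, seed = 2)
  truth <- sim$cell_meta[rownames(res$cells), "cluster"]
  expect_gte(adjusted_rand_index(res$clusters, truth), 0.9)
  # determinism end to end
  res2 <- cluster_cells(sim$cells, n_hvgs = 300, n_components = 10, k = 9,
                        resolution = 0.3, seed = 2)
  expect_identical(res$clusters, res2$clusters)
})

test_that("pseudobulk sums are exact and the cell floor applies", {
  cells <- matrix(1:12, 4, 3,
                  dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  storage.mode(cells) <- "integer"
  pb <- pseudobulk(cells, c("x", "x", "y", "y"), min_cells = 2)
  expect_identical(unname(pb$counts[, "x"]), as.integer(colSums(cells[1:2, ])))
  expect_identical(unname(pb$counts[, "y"]), as.integer(colSums(cells[3:4, ])))
  single <- pseudobulk(cells, rep("all", 4), min_cells = 4)
  expect_identical(unname(single$counts[, 1]), as.integer(colSums(cells)))
  # group of 9 at floor 10 dropped
  big <- matrix(1L, 19, 2, dimnames = list(paste0("c", 1:19), c("g1", "g2")))
  expect_message(pb2 <- pseudobulk(big, rep(c("a", "b"), c(10, 9))), "dropping")
  expect_identical(colnames(pb2$counts), "a")
  expect_error(pseudobulk(big, rep(c("a", "b"), c(10, 9)), min_cells = 50),
               "floor")
  # conservation: group totals sum to the total over retained cells
  pb3 <- pseudobulk(cells, c("x", "x", "y", "y"), min_cells = 1)
  expect_identical(sum(pb3$counts), sum(cells))
})

test_that("pseudobulk DE recovers planted cluster markers", {
  sim <- small_sc(seed = 21)
  meta <- sim$cell_meta
  pb <- pseudobulk(sim$cells,
                   data.frame(cluster = meta$cluster, donor = meta$donor),
                   min_cells = 10)
  names(pb$meta) <- c("cluster", "donor")
  res <- pseudobulk_de(pb, cluster_a = "1", cluster_b = "2")
  d <- attr(res, "directions")
  called_up <- names(d)[d == 1L]
  called_dn <- names(d)[d == -1L]
  m1 <- sim$truth$markers[[1]]; m2 <- sim$truth$markers[[2]]
  expect_gte(recall_of(called_up, intersect(m1, names(d))), 0.8)
  expect_gte(recall_of(called_dn, intersect(m2, names(d))), 0.8)
  expect_gte(precision_of(c(called_up, called_dn), c(m1, m2)), 0.8)
})

test_that("identical clusters yield (almost) no pseudobulk DE calls", {
  sim <- small_sc(seed = 31)
  meta <- sim$cell_meta
  only1 <- rownames(meta)[meta$cluster == 1]
  cells <- sim$cells[only1, ]
  set.seed(77)
  fake <- sample(c("1", "2"), length(only1), replace = TRUE)
  pb <- pseudobulk(cells, data.frame(cluster = fake,
                                     donor = meta[only1, "donor"]),
                   min_cells = 5)
  names(pb$meta) <- c("cluster", "donor")
  res <- pseudobulk_de(pb, "1", "2")
  d <- attr(res, "directions")
  expect_lte(mean(d != 0L), 0.01)
})

test_that("CLR normalization centres each cell and matches hand arithmetic", {
  x <- rbind(c1 = c(1L, 3L), c2 = c(10L, 10L))
  colnames(x) <- c("tagA", "tagB")
  v <- clr_normalize_protein(x, pseudo = 1)
  expect_equal(unname(v["c1", ]), c(log(2 / sqrt(8)), log(4 / sqrt(8))),
               tolerance = 1e-12)
  expect_equal(unname(v["c1", ]), c(-0.3466, 0.3466), tolerance = 1e-4)
  expect_true(all(v["c2", ] == 0))                 # constant vector
  set.seed(12)
  big <- matrix(rpois(600, 20), 30, 20,
                dimnames = list(paste0("c", 1:30), paste0("t", 1:20)))
  expect_true(all(abs(rowSums(clr_normalize_protein(big))) < 1e-9))
})
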