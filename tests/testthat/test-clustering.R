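# single-cell table built directly from generator ground truth (true
# per-cell marker means), bypassing imaging: isolates the clustering logic
truthTable <- function(truth) {
  tab <- truth$cell_table
  markers <- sub("^mean_", "", grep("^mean_", names(tab), value = TRUE))
  m <- t(as.matrix(tab[, paste0("mean_", markers)]))
  rownames(m) <- markers
  SingleCellTable(m, data.frame(cell_id = tab$cell_id, fov = tab$fov,
                                area = tab$area,
                                centroid_row = tab$centroid_row,
                                centroid_col = tab$centroid_col))
}

clusterMixture <- c("CD4+ T cells" = 0.3, "B cells" = 0.25,
                    "Neutrophils" = 0.25, "Tumor cells" = 0.2)

test_that("the embedding is shaped, seeded and separates phenotypes", {
  cfg <- syntheticConfig(n_cycles = 4L, n_fovs = 1L,
                         image_shape = c(512L, 512L), n_cells = 300L,
                         phenotype_mixture = clusterMixture, seed = 51L)
  g <- generateDataset(cfg)
  tab <- logTransform(truthTable(g$truth))
  emb <- embedCells(tab, seed = 7)
  expect_equal(dim(emb$coords), c(ncol(tab), 2L))
  emb2 <- embedCells(tab, seed = 7)
  expect_identical(emb$coords, emb2$coords)
  # separability: planted phenotypes have a positive silhouette in the
  # embedding
  ph <- factor(g$truth$cell_table$phenotype)
  sil <- cluster::silhouette(as.integer(ph), dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0)
  expect_error(embedCells(tab[, 1:10], n_neighbors = 15), "n_neighbors")
})

test_that("density clustering finds planted blobs and labels noise", {
  set.seed(9)
  X2 <- rbind(matrix(rnorm(400, 0, 0.5), ncol = 2),
              matrix(rnorm(400, 8, 0.5), ncol = 2))
  r2 <- hdbscan(X2, min_cluster_size = 20)
  expect_equal(r2$n_clusters, 2L)
  expect_equal(r2$n_clusters, length(setdiff(unique(r2$cluster), -1L)))
  # the split separates the planted blobs
  expect_equal(length(unique(r2$cluster[1:200][r2$cluster[1:200] > 0])), 1L)

  one <- matrix(rnorm(300, 0, 0.4), ncol = 2)
  expect_equal(hdbscan(one, min_cluster_size = 20)$n_clusters, 1L)

  allnoise <- hdbscan(one, min_cluster_size = 500)
  expect_equal(allnoise$n_clusters, 0L)
  expect_true(all(allnoise$cluster == -1L))
})

test_that("cluster ids are a pure relabeling under permutation", {
  set.seed(10)
  X <- rbind(matrix(rnorm(300, 0, 0.5), ncol = 2),
             matrix(rnorm(300, 6, 0.5), ncol = 2))
  perm <- sample(nrow(X))
  a <- hdbscan(X, min_cluster_size = 15)$cluster
  b <- hdbscan(X[perm, ], min_cluster_size = 15)$cluster
  # partitions agree up to label names
  expect_equal(mclust::adjustedRandIndex(a[perm], b), 1)
})

test_that("cluster profiles are per-marker z-scored cluster means", {
  set.seed(12)
  x <- rbind(A = rnorm(40, 2), B = rnorm(40, -1))
  tab <- SingleCellTable(x, data.frame(cell_id = 1:40, fov = 1, area = 1,
                                       centroid_row = 1, centroid_col = 1),
                         transformState = "log")
  onecl <- clusterProfiles(tab, rep(1L, 40))
  raw <- attr(onecl, "raw_means")
  expect_equal(unname(raw["1", ]), unname(rowMeans(x)))

  cl <- rep(c(1L, 2L), each = 20)
  two <- clusterProfiles(tab, cl)
  raw2 <- attr(two, "raw_means")
  expect_equal(unname(raw2["1", "A"]), mean(x["A", 1:20]))
  expect_equal(unname(raw2["2", "B"]), mean(x["B", 21:40]))
  expect_equal(unname(colMeans(two)), c(0, 0), tolerance = 1e-12)
  # noise cells excluded
  cln <- cl; cln[1:5] <- -1L
  rawn <- attr(clusterProfiles(tab, cln), "raw_means")
  expect_equal(unname(rawn["1", "A"]), mean(x["A", 6:20]))
  expect_error(clusterProfiles(tab, rep(-1L, 40)), "noise")
})

test_that("composition tables conserve phenotype marginals", {
  ph <- rep(c("T", "B"), c(30, 20))
  cl <- c(rep(1L, 28), rep(2L, 2), rep(2L, 15), rep(-1L, 5))
  comp <- composition(cl, ph)
  expect_equal(sum(comp$counts), 50)
  expect_equal(unname(rowSums(comp$counts)), c(20, 30)) # alphabetical rows
  expect_equal(unname(comp$counts["T", "1"]), 28)
  expect_equal(unname(comp$counts["B", "-1"]), 5)
  expect_equal(unname(rowSums(comp$fractions)), c(1, 1))
  single <- composition(rep(1L, 7), rep("T", 7))
  expect_equal(unname(single$counts[1, 1]), 7)
})
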