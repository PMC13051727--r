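test_that("three points at mutual distances 1,1,2 merge pair-first, root at 2", {
  # collinear points 0, 1, 2: d(1,2)=d(2,3)=1, d(1,3)=2
  x <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("c", 1:3), "g"))
  hc <- hierarchical_clustergram(x, "cells")
  expect_equal(hc$height, c(1, 2))  # complete linkage: final merge at the max distance
  expect_error(hierarchical_clustergram(x[1, , drop = FALSE], "cells"), "at least 2")
})

test_that("duplicated rows merge at height 0 and gene-axis clustering works", {
  x <- matrix(c(1, 1, 5, 2, 2, 9), 3, 2,
              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  hc <- hierarchical_clustergram(x, "cells")
  expect_equal(min(hc$height), 0)
  hcg <- hierarchical_clustergram(x, "genes")
  expect_equal(length(hcg$order), 2)
})

test_that("complete-linkage merge heights match a brute-force O(n^3) oracle", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(paste0("c", 1:10), NULL))
    hc <- hierarchical_clustergram(x, "cells")
    expect_equal(sort(hc$height), oracle_complete_linkage_heights(x), tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  }
})

test_that("k-means recovers two well-separated blobs exactly", {
  x <- two_blobs(n_per = 20, sep = 10, sd = 1)
  m <- kmeans_partition(x, 2, seed = 3)
  planted <- rep(1:2, each = 20)
  expect_equal(length(unique(paste(m$assignment, planted))), 2)  # label permutation of planted
  expect_equal(m$sizes, c(20L, 20L))
})

test_that("k = 1 gives the total sum of squared deviations from the grand centroid", {
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("c", 1:10), NULL))
  m <- kmeans_partition(x, 1, seed = 1, n_init = 2)
  expect_equal(m$wcss, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)
})

test_that("k-means WCSS equals the exhaustive-partition minimum on small problems", {
  set.seed(31)
  x8 <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("c", 1:8), NULL))
  m <- kmeans_partition(x8, 2, seed = 1, n_init = 50)
  expect_equal(m$wcss, oracle_min_wcss(x8, 2), tolerance = 1e-9)
  x7 <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("c", 1:7), NULL))
  m3 <- kmeans_partition(x7, 3, seed = 1, n_init = 50)
  expect_equal(m3$wcss, oracle_min_wcss(x7, 3), tolerance = 1e-9)
})

test_that("model invariants hold: non-empty clusters, member-mean centroids, exact wcss", {
  sim <- generate_ct(synthetic_spec(n_plates = 1, wells_per_plate = 60, seed = 2))
  e <- pooled_median_normalize(sim$ct)
  m <- kmeans_partition(e, 4, seed = 7, n_init = 10)
  expect_true(all(m$sizes > 0))
  for (j in 1:4) {
    expect_equal(m$centroids[j, ],
                 colMeans(e$expr[m$assignment == j, , drop = FALSE]))
  }
  recomputed <- sum((e$expr - m$centroids[m$assignment, ])^2)
  expect_equal(m$wcss, recomputed, tolerance = 1e-9)
  # Lloyd local optimality: no single cell is closer to another centroid
  d2 <- sapply(1:4, function(j) rowSums(sweep(e$expr, 2, m$centroids[j, ])^2))
  expect_true(all(abs(d2[cbind(seq_len(nrow(d2)), m$assignment)] -
                        apply(d2, 1, min)) < 1e-9))
})

test_that("k-means is reproducible given seed, and more restarts never worsen wcss", {
  x <- two_blobs(12, sep = 3, sd = 1.5, seed = 4)
  a <- kmeans_partition(x, 3, seed = 11, n_init = 5)
  b <- kmeans_partition(x, 3, seed = 11, n_init = 5)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$wcss, b$wcss)
  w <- sapply(c(1, 5, 25), function(ni) kmeans_partition(x, 3, seed = 11, n_init = ni)$wcss)
  expect_true(all(diff(w) <= 1e-12))
  expect_error(kmeans_partition(x, nrow(x) + 1, seed = 1), "exceeds")
})

test_that("silhouette selection finds four planted clusters and flags a null cloud", {
  spec <- synthetic_spec(n_plates = 2, wells_per_plate = 96, dropout = 0,
                         prop_b = c(0.30, 0.25, 0.25, 0.20), seed = 13)
  e <- pooled_median_normalize(generate_ct(spec)$ct)
  sel <- select_k(e, 2:6, seed = 1, n_init = 10)
  expect_equal(sel$k, 4L)
  expect_false(sel$no_structure)
  expect_equal(nrow(sel$diagnostics), 5)
  # homogeneous cloud: low silhouette everywhere, flagged as structureless
  set.seed(14)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(paste0("c", 1:60), NULL))
  sel0 <- select_k(x, 2:5, seed = 1, n_init = 5)
  expect_true(sel0$no_structure)
  expect_true(all(sel0$diagnostics$silhouette < 0.25))
})

test_that("duplicating every cell leaves the selected k unchanged", {
  x <- two_blobs(15, sep = 8, sd = 1, seed = 5)
  sel1 <- select_k(x, 2:4, seed = 2, n_init = 5)
  xd <- rbind(x, x)
  rownames(xd) <- paste0("c", seq_len(nrow(xd)))
  sel2 <- select_k(xd, 2:4, seed = 2, n_init = 5)
  expect_equal(sel1$k, sel2$k)
})

test_that("identical cells degenerate to k = 1 with a warning", {
  x <- matrix(1, 10, 3, dimnames = list(paste0("c", 1:10), NULL))
  expect_warning(sel <- select_k(x, 2:3), "identical")
  expect_equal(sel$k, 1L)
})

test_that("subgroup order is a cluster-contiguous permutation, singletons untouched", {
  x <- two_blobs(10, sep = 9, sd = 1, seed = 6)
  m <- kmeans_partition(x, 2, seed = 1, n_init = 5)
  ord <- subgroup_order(x, m)
  expect_setequal(ord, seq_len(nrow(x)))
  runs <- rle(as.integer(m$assignment[ord]))
  expect_equal(length(runs$lengths), m$k)  # one contiguous block per cluster
  expect_identical(ord, m$leaf_order)
  # all-singleton clusters: order is just a permutation of the cells
  xs <- matrix(c(0, 10, 20), 3, 1, dimnames = list(paste0("c", 1:3), NULL))
  ms <- kmeans_partition(xs, 3, seed = 1, n_init = 3)
  expect_setequal(subgroup_order(xs, ms), 1:3)
})

test_that("planted-cluster recovery is high on default-strength synthetic data", {
  skip_if_not_installed("mclust")
  ok <- 0
  for (s in 1:10) {
    sim <- generate_ct(synthetic_spec(n_plates = 2, wells_per_plate = 96, seed = 100 + s))
    wt <- sim$truth$cells$group == "WT"
    e <- subset_cells(pooled_median_normalize(sim$ct), wt)
    m <- kmeans_partition(e, 4, seed = 1, n_init = 20)
    ari <- mclust::adjustedRandIndex(m$assignment, sim$truth$cells$cluster[wt])
    if (ari >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
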