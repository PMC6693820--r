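test_that("classical MDS reconstructs Euclidean-realizable distances", {
  ## four corners of the unit square
  P <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(P))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  X <- classical_mds(D, dims = 3)
  expect_equal(dim(X), c(4L, 3L))
  expect_equal(as.matrix(dist(X)), unname(D), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(X, "n_clipped"), 0L)
  ## cross-check against the stats implementation
  X2 <- stats::cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(X)), as.matrix(dist(X2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## random Euclidean configurations reconstruct too
  set.seed(71)
  P <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(P))
  dimnames(D) <- list(paste0("q", 1:10), paste0("q", 1:10))
  expect_equal(as.matrix(dist(classical_mds(D, 5))), unname(D),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MDS degrades gracefully on degenerate and non-metric input", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  X <- classical_mds(Z, dims = 3)
  expect_true(all(X == 0))                      # all points at the origin
  ## triangle-inequality violation: d(a,c) >> d(a,b) + d(b,c)
  D <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_message(X2 <- classical_mds(D, dims = 3), "clipped")
  expect_gt(attr(X2, "n_clipped"), 0)
  expect_true(all(is.finite(X2)))
  expect_error(classical_mds(D[1:2, 1:2]), "at least 3")
})

test_that("t-SNE is deterministic per seed and improves with restarts", {
  set.seed(72)
  X <- rbind(matrix(rnorm(60, 0, .3), ncol = 3),
             matrix(rnorm(60, 6, .3), ncol = 3))
  rownames(X) <- paste0("p", 1:40)
  e1 <- suppressWarnings(tsne_embed(X, n_restarts = 1, seed = 9,
                                    max_iter = 300))
  e1b <- suppressWarnings(tsne_embed(X, n_restarts = 1, seed = 9,
                                     max_iter = 300))
  expect_identical(e1$tsne_coords, e1b$tsne_coords)
  e5 <- suppressWarnings(tsne_embed(X, n_restarts = 5, seed = 9,
                                    max_iter = 300))
  expect_lte(e5$kl_divergence, e1$kl_divergence)   # min over a superset
  expect_equal(e5$kl_divergence, min(e5$kl_all))
  ## two well-separated groups stay separated in the embedding
  Y <- e5$tsne_coords
  grp <- rep(1:2, each = 20)
  centroid_gap <- sqrt(sum((colMeans(Y[grp == 1, ]) -
                            colMeans(Y[grp == 2, ]))^2))
  within_mean <- mean(c(dist(Y[grp == 1, ]), dist(Y[grp == 2, ])))
  expect_gt(centroid_gap, within_mean)
  ## perplexity is reduced with a warning when n is small
  expect_warning(tsne_embed(X[1:20, ], n_restarts = 1, seed = 1,
                            max_iter = 100), "perplexity reduced")
})

test_that("OPTICS separates Gaussian blobs and agrees with a DBSCAN oracle", {
  set.seed(73)
  sigma <- 0.4
  X <- rbind(matrix(rnorm(90, 0, sigma), ncol = 3),
             matrix(rnorm(90, 10 * sigma * sqrt(3), sigma), ncol = 3))
  rownames(X) <- paste0("p", 1:60)
  truth <- rep(0:1, each = 30)
  ## threshold extraction finds the two blobs and reproduces a DBSCAN
  ## oracle exactly at matching eps
  orc <- dbscan_oracle(X, eps = 6 * sigma, min_pts = 5)
  cl_thr <- optics_clusters(X, min_samples = 5, method = "threshold",
                            eps = 6 * sigma)
  expect_equal(length(unique(cl_thr$labels[cl_thr$labels >= 0])), 2L)
  expect_gte(ari(cl_thr$labels, truth), 0.95)
  expect_equal(ari(cl_thr$labels, orc), 1)
  ## xi extraction may carve a blob into sub-clusters but never mixes the
  ## blobs: each extracted cluster is pure
  cl_xi <- optics_clusters(X, min_samples = 5, xi = 0.05)
  found <- cl_xi$labels
  expect_gte(length(unique(found[found >= 0])), 2L)
  for (cid in unique(found[found >= 0])) {
    expect_equal(length(unique(truth[found == cid])), 1L)
  }
  ## and both blobs are represented among the clustered points
  expect_setequal(unique(truth[found >= 0]), 0:1)
})

test_that("sparse uniform points are all noise under a strict threshold", {
  set.seed(74)
  X <- matrix(runif(90, 0, 100), ncol = 3)
  rownames(X) <- paste0("p", 1:30)
  cl <- optics_clusters(X, min_samples = 5, method = "threshold", eps = 0.5)
  expect_true(all(cl$labels == -1L))
})

test_that("clustering output is structurally sound and reproducible", {
  set.seed(75)
  X <- rbind(matrix(rnorm(60, 0, .5), ncol = 3),
             matrix(rnorm(60, 8, .5), ncol = 3))
  rownames(X) <- paste0("p", 1:40)
  c1 <- optics_clusters(X)
  c2 <- optics_clusters(X)
  expect_identical(c1$labels, c2$labels)        # deterministic
  expect_identical(c1$ordering, c2$ordering)
  labs <- c1$labels[c1$labels >= 0]
  expect_identical(sort(unique(labs)), seq(0L, max(labs)))  # contiguous ids
  expect_equal(length(c1$reachability), nrow(X))
  ## drill-down re-clustering runs the same machinery on one cluster
  sub <- subcluster(X, c1, 0L, min_samples = 5)
  expect_equal(length(sub$labels), sum(c1$labels == 0L))
})

test_that("cluster dendrograms use mean inter-cluster distance, UPGMA", {
  ## two tight singleton-ish clusters: single merge at the mean distance
  X <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(5, 0, 0), c(5.2, 0, 0))
  rownames(X) <- paste0("p", 1:4)
  labels <- c(0L, 0L, 1L, 1L)
  d <- cluster_dendrogram(X, labels)
  expect_equal(length(d$heights), 1L)
  expect_equal(d$heights, mean(c(5, 5.2, 4.8, 5)))
  expect_match(d$newick, "^\\(")
  ## three collinear clusters at ~0, ~1 and ~10: nearest pair merges first
  X3 <- cbind(c(-0.05, 0.05, 0.95, 1.05, 9.95, 10.05), 0, 0)
  rownames(X3) <- paste0("q", 1:6)
  lab3 <- c(0L, 0L, 1L, 1L, 2L, 2L)
  d3 <- cluster_dendrogram(X3, lab3)
  first <- sort(-d3$merges[1, ])
  expect_equal(first, c(1, 2))                  # clusters 0 and 1 first
  expect_true(all(diff(d3$heights) >= 0))       # monotone heights
  ## noise is excluded from the tree
  d4 <- cluster_dendrogram(rbind(X, c(50, 50, 50)),
                           c(labels, -1L))
  expect_equal(length(d4$leaves), 2L)
})
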