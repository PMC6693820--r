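#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, B = -1/2 J D^2 J, and takes
#' coordinates from the leading eigenpairs. The combined genome distance is
#' noisy and violates the triangle inequality, so negative eigenvalues are
#' expected: they are clipped to zero, their count reported via
#' `attr(, "n_clipped")` and a message, and the corresponding columns left
#' at zero. When fewer than `dims` positive eigenvalues exist the remaining
#' columns are zero, so the output always has `dims` columns.
#'
#' @param matrix Finite symmetric zero-diagonal distance matrix, n >= 3.
#' @param dims Target dimension, default 50.
#' @return n x dims coordinate matrix, rownames = ids; attributes
#'   `eigenvalues`, `n_clipped`.
#' @export
classical_mds <- function(matrix, dims = 50L) {
  n <- nrow(matrix)
  if (n < 3) stop("classical MDS needs at least 3 points")
  stopifnot(all(is.finite(matrix)), isTRUE(all.equal(matrix, t(matrix))),
            all(diag(matrix) == 0))
  D2 <- matrix^2
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  scale_tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > scale_tol
  n_clipped <- sum(e$values < -scale_tol)   # ignore numerical dust
  k <- min(dims, sum(pos))
  X <- matrix(0, n, dims, dimnames = list(rownames(matrix), NULL))
  if (k > 0) {
    X[, seq_len(k)] <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  }
  if (n_clipped > 0) {
    message(n_clipped, " negative MDS eigenvalue(s) clipped to zero")
  }
  attr(X, "eigenvalues") <- e$values
  attr(X, "n_clipped") <- n_clipped
  X
}

#' Barnes-Hut t-SNE embedding with restarts
#'
#' Embeds the MDS coordinates in `out_dims` dimensions with Barnes-Hut
#' t-SNE (perplexity 30, theta 0.5 by default). The optimisation is run
#' `n_restarts` times (restart r seeded with `seed + r - 1`) and the run
#' with the lowest final Kullback-Leibler divergence is kept. Local
#' neighbourhoods survive the embedding; global geometry does not, which is
#' the intended trade-off for density clustering.
#'
#' @param coords n x d coordinate matrix (rownames = ids).
#' @param perplexity t-SNE perplexity; when `n < 3 * perplexity + 1` it is
#'   reduced to `floor((n - 1) / 3)` with a warning.
#' @param theta Barnes-Hut accuracy trade-off (0 = exact).
#' @param n_restarts Number of random restarts, default 20.
#' @param out_dims Embedding dimension, default 3 (at most 3).
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations per restart.
#' @return List of class `virtaxa_embedding`: `ids`, `mds_coords`,
#'   `tsne_coords` (n x out_dims), `kl_divergence` (the minimum across
#'   restarts), `kl_all`, `seed`, `n_restarts`, `perplexity`.
#' @export
tsne_embed <- function(coords, perplexity = 30, theta = 0.5,
                       n_restarts = 20L, out_dims = 3L, seed = 1L,
                       max_iter = 1000L) {
  n <- nrow(coords)
  stopifnot(out_dims >= 1, out_dims <= 3, n_restarts >= 1)
  if (n - 1 < 3 * perplexity) {
    perplexity <- floor((n - 1) / 3)
    warning("perplexity reduced to ", perplexity, " for n = ", n,
            call. = FALSE)
  }
  if (perplexity < 1) stop("too few points for t-SNE")
  best <- NULL
  kl_all <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- Rtsne::Rtsne(coords, dims = out_dims, perplexity = perplexity,
                        theta = theta, pca = FALSE, max_iter = max_iter,
                        check_duplicates = FALSE, verbose = FALSE)
    kl_all[r] <- tail(fit$itercosts, 1)
    if (is.null(best) || kl_all[r] < best$kl) {
      best <- list(kl = kl_all[r], Y = fit$Y)
    }
  }
  rownames(best$Y) <- rownames(coords)
  structure(list(ids = rownames(coords), mds_coords = coords,
                 tsne_coords = best$Y, kl_divergence = best$kl,
                 kl_all = kl_all, seed = seed, n_restarts = n_restarts,
                 perplexity = perplexity),
            class = "virtaxa_embedding")
}

#' Average-linkage dendrogram over clusters
#'
#' Clusters are merged agglomeratively using the mean pairwise Euclidean
#' distance between their members in the embedding space (UPGMA); noise
#' points are excluded. Branch lengths read as how much more similar a
#' cluster is to itself than to the rest — a confidence score, not an
#' evolutionary time.
#'
#' @param coords n x d embedding coordinates (rownames = ids).
#' @param clustering A `virtaxa_clustering` from [optics_clusters()], or
#'   any integer label vector aligned with `coords` rows (-1 = noise).
#' @return List of class `virtaxa_dendrogram`: `leaves` (cluster ids),
#'   `merges`, `heights`, the underlying `hclust`, and `newick`.
#' @export
cluster_dendrogram <- function(coords, clustering) {
  labels <- if (is.list(clustering)) clustering$labels else clustering
  stopifnot(length(labels) == nrow(coords))
  keep <- labels >= 0
  labs <- labels[keep]
  X <- coords[keep, , drop = FALSE]
  cl <- sort(unique(labs))
  if (length(cl) < 2) stop("need at least 2 clusters for a dendrogram")
  sizes <- as.numeric(table(factor(labs, levels = cl)))
  M <- matrix(0, length(cl), length(cl),
              dimnames = list(paste0("cluster_", cl), paste0("cluster_", cl)))
  full <- as.matrix(dist(X))
  for (i in seq_along(cl)[-1]) {
    for (j in seq_len(i - 1)) {
      M[i, j] <- M[j, i] <- mean(full[labs == cl[i], labs == cl[j]])
    }
  }
  hc <- hclust(as.dist(M), method = "average", members = sizes)
  phy <- ape::as.phylo(hc)
  structure(list(leaves = cl, merges = hc$merge, heights = hc$height,
                 hclust = hc, newick = ape::write.tree(phy)),
            class = "virtaxa_dendrogram")
}
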