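## OPTICS density-based clustering (Ankerst et al. 1999), with xi-style
## hierarchical cluster extraction and a DBSCAN-style reachability
## threshold extraction. O(n^2) with eps = Inf, which is the regime used
## here: a few thousand embedded genomes at most.

optics_order <- function(X, min_samples) {
  n <- nrow(X)
  stopifnot(min_samples >= 2, n >= min_samples)
  D <- as.matrix(dist(X))
  ## core distance: distance to the min_samples-th nearest point, the point
  ## itself included
  core <- apply(D, 1, function(d) sort(d)[min_samples])
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ordering <- integer(n)
  for (pos in seq_len(n)) {
    unproc <- which(!processed)
    p <- unproc[which.min(reach[unproc])]
    processed[p] <- TRUE
    ordering[pos] <- p
    rest <- which(!processed)
    if (length(rest)) {
      new_reach <- pmax(core[p], D[p, rest])
      upd <- new_reach < reach[rest]
      reach[rest[upd]] <- new_reach[upd]
      pred[rest[upd]] <- p
    }
  }
  list(ordering = ordering, reachability = reach, core_distances = core,
       predecessor = pred)
}

xi_extend_region <- function(steep, xward, start, min_samples) {
  n <- length(steep)
  non_xward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep[index]) {
      non_xward <- 0L
      end <- index
    } else if (!xward[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_samples) break
    } else {
      return(end)
    }
    index <- index + 1L
  }
  end
}

xi_update_sdas <- function(sdas, mib, xi_complement, r) {
  if (is.infinite(mib)) return(list())
  keep <- vapply(sdas, function(s) mib <= r[s$start] * xi_complement, TRUE)
  sdas <- sdas[keep]
  lapply(sdas, function(s) {
    s$mib <- max(s$mib, mib)
    s
  })
}

xi_correct_predecessor <- function(r, pred_plot, ordering, s, e) {
  while (s < e) {
    if (r[s] > r[e]) return(c(s, e))
    p_e <- pred_plot[e]
    if (!is.na(p_e) && s <= e - 1 && p_e %in% ordering[s:(e - 1)]) {
      return(c(s, e))
    }
    e <- e - 1L
  }
  NULL
}

## returns a list of (start, end) index pairs in ordering space, smaller
## (nested) clusters before the clusters that contain them
xi_cluster <- function(reach_plot, pred_plot, ordering, xi, min_samples,
                       min_cluster_size) {
  n <- length(reach_plot)
  r <- c(reach_plot, Inf)
  xi_c <- 1 - xi
  ratio <- r[seq_len(n)] / r[seq_len(n) + 1]
  steep_up <- !is.na(ratio) & ratio <= xi_c
  steep_down <- !is.na(ratio) & ratio >= 1 / xi_c
  upward <- !is.na(ratio) & ratio < 1
  downward <- !is.na(ratio) & ratio > 1
  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  for (steep_index in which(steep_up | steep_down)) {
    if (steep_index < index) next
    mib <- max(mib, max(r[index:steep_index]))
    if (steep_down[steep_index]) {
      sdas <- xi_update_sdas(sdas, mib, xi_c, r)
      D_start <- steep_index
      D_end <- xi_extend_region(steep_down, upward, D_start, min_samples)
      sdas[[length(sdas) + 1L]] <- list(start = D_start, end = D_end,
                                        mib = 0)
      index <- D_end + 1L
      mib <- r[index]
    } else {
      sdas <- xi_update_sdas(sdas, mib, xi_c, r)
      U_start <- steep_index
      U_end <- xi_extend_region(steep_up, downward, U_start, min_samples)
      index <- U_end + 1L
      mib <- r[index]
      U_clusters <- list()
      for (D in sdas) {
        c_start <- D$start
        c_end <- U_end
        if (r[c_end + 1] * xi_c < D$mib) next
        D_max <- r[D$start]
        if (D_max * xi_c >= r[c_end + 1]) {
          while (r[c_start + 1] > r[c_end + 1] && c_start < D$end) {
            c_start <- c_start + 1L
          }
        } else if (r[c_end + 1] * xi_c >= D_max) {
          while (r[c_end - 1] > D_max && c_end > U_start) {
            c_end <- c_end - 1L
          }
        }
        ce <- xi_correct_predecessor(r, pred_plot, ordering, c_start, c_end)
        if (is.null(ce)) next
        c_start <- ce[1]; c_end <- ce[2]
        if (c_end - c_start + 1 < min_cluster_size) next
        if (c_start > D$end) next
        if (c_end < U_start) next
        U_clusters[[length(U_clusters) + 1L]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(U_clusters))
    }
  }
  clusters
}

xi_labels <- function(ordering, clusters) {
  n <- length(ordering)
  lab_o <- rep(-1L, n)
  label <- 0L
  for (cc in clusters) {
    span <- cc[1]:cc[2]
    if (all(lab_o[span] == -1L)) {
      lab_o[span] <- label
      label <- label + 1L
    }
  }
  labels <- integer(n)
  labels[ordering] <- lab_o
  labels
}

dbscan_labels <- function(ordering, reach, core, eps) {
  n <- length(ordering)
  lab_o <- rep(-1L, n)
  cl <- -1L
  reach_o <- reach[ordering]
  core_o <- core[ordering]
  for (pos in seq_len(n)) {
    if (reach_o[pos] > eps) {
      if (core_o[pos] <= eps) {
        cl <- cl + 1L
        lab_o[pos] <- cl
      }
    } else {
      lab_o[pos] <- cl
    }
  }
  labels <- integer(n)
  labels[ordering] <- lab_o
  labels
}

#' OPTICS density clustering of an embedding
#'
#' Computes the OPTICS reachability ordering of the embedded points
#' (eps = Inf) and extracts flat clusters either from steep areas of the
#' reachability plot (`method = "xi"`, the default) or by cutting the plot
#' at a fixed reachability (`method = "threshold"`, DBSCAN-equivalent).
#' Points in no cluster are labelled noise (-1).
#'
#' @param coords n x d coordinate matrix (rownames = ids), typically the
#'   3-D t-SNE embedding.
#' @param min_samples Minimum neighbourhood size defining density
#'   (default 5).
#' @param method `"xi"` or `"threshold"`.
#' @param xi Minimum relative steepness delimiting a cluster boundary
#'   (default 0.05).
#' @param eps Reachability cut for `method = "threshold"`.
#' @param min_cluster_size Smallest extractable cluster (default
#'   `min_samples`).
#' @return List of class `virtaxa_clustering`: `ids`, `labels` (integer,
#'   -1 = noise, cluster ids contiguous from 0), `reachability`,
#'   `ordering`, `core_distances`, `predecessor`, `params`.
#' @export
optics_clusters <- function(coords, min_samples = 5L,
                            method = c("xi", "threshold"), xi = 0.05,
                            eps = NULL, min_cluster_size = NULL) {
  method <- match.arg(method)
  if (is.null(min_cluster_size)) min_cluster_size <- min_samples
  o <- optics_order(coords, min_samples)
  if (method == "xi") {
    clusters <- xi_cluster(o$reachability[o$ordering],
                           o$predecessor[o$ordering], o$ordering,
                           xi, min_samples, min_cluster_size)
    labels <- xi_labels(o$ordering, clusters)
  } else {
    if (is.null(eps)) stop("method = 'threshold' requires eps")
    labels <- dbscan_labels(o$ordering, o$reachability, o$core_distances,
                            eps)
  }
  ## relabel so that cluster ids are contiguous from 0
  pos <- labels >= 0
  if (any(pos)) {
    labels[pos] <- as.integer(factor(labels[pos])) - 1L
  }
  structure(list(ids = rownames(coords), labels = labels,
                 reachability = o$reachability, ordering = o$ordering,
                 core_distances = o$core_distances,
                 predecessor = o$predecessor,
                 params = list(min_samples = min_samples, method = method,
                               xi = xi, eps = eps,
                               min_cluster_size = min_cluster_size)),
            class = "virtaxa_clustering")
}

#' Re-cluster the members of one cluster
#'
#' Drill-down analysis: the members of a single cluster are re-embedded
#' points already, so sub-structure is found by running OPTICS again on
#' just those rows, with the same operations and no special casing.
#'
#' @param coords Embedding coordinates for the full corpus.
#' @param clustering A `virtaxa_clustering` on those coordinates.
#' @param cluster_id The cluster to drill into.
#' @param ... Passed to [optics_clusters()].
#' @return A `virtaxa_clustering` over the member subset.
#' @export
subcluster <- function(coords, clustering, cluster_id, ...) {
  keep <- clustering$labels == cluster_id
  if (sum(keep) < 3) stop("cluster ", cluster_id, " is too small to split")
  optics_clusters(coords[keep, , drop = FALSE], ...)
}
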