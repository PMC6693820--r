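#' Fit a k-NN reference model from a clustered corpus
#'
#' Freezes the corpus 4-mer baseline and the per-genome over/under
#' representation flags, and keeps the cluster label of every non-noise
#' genome. New genomes are later compared against this frozen state only;
#' adding them does not move the baseline.
#'
#' @param corpus The reference [corpus()].
#' @param clustering A `virtaxa_clustering` over that corpus (or an integer
#'   label vector, -1 = noise).
#' @param k Word size for the k-mer representation, default 4.
#' @return List of class `virtaxa_reference`: `baseline`, `flags` (logical
#'   matrix, reference genomes x 4^k), `p_over`, `labels` (named integer),
#'   `cluster_sizes`, `k`.
#' @export
fit_reference <- function(corpus, clustering, k = 4L) {
  labels <- if (is.list(clustering)) clustering$labels else clustering
  ids <- genome_ids(corpus)
  stopifnot(length(labels) == length(ids))
  base <- corpus_baseline(corpus, k)
  keep <- labels >= 0
  reps <- lapply(corpus$genomes[keep], function(g) {
    representation_flags(count_kmers(g$nt_sequence, k), base)
  })
  flags <- do.call(rbind, lapply(reps, `[[`, "flags"))
  rownames(flags) <- ids[keep]
  labs <- setNames(as.integer(labels[keep]), ids[keep])
  structure(list(baseline = base, flags = flags,
                 p_over = vapply(reps, `[[`, 0, "p_over"),
                 labels = labs,
                 cluster_sizes = table(labs), k = k),
            class = "virtaxa_reference")
}

## VI in bits between one flag vector and each row of a flag matrix
vi_to_reference <- function(flags, ref_flags) {
  m <- ncol(ref_flags)
  oo <- as.numeric(ref_flags %*% flags) / m
  pa <- rowMeans(ref_flags)
  pb <- mean(flags)
  ou <- pa - oo; uo <- pb - oo; uu <- 1 - pa - pb + oo
  Ha <- vapply(pa, binary_entropy, 0)
  Hb <- binary_entropy(pb)
  I <- numeric(nrow(ref_flags))
  cells <- cbind(oo, ou, uo, uu)
  marg <- cbind(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  nz <- cells > 0
  I <- rowSums(ifelse(nz, cells * log2(cells / marg), 0))
  pmax(Ha + Hb - 2 * I, 0)
}

#' Place new genomes into an existing clustering by weighted k-NN
#'
#' Each new genome's 4-mer flags are computed against the frozen reference
#' baseline; its k nearest reference genomes by k-mer variation of
#' information vote for their clusters with weight `weighting(cluster
#' size)`. The default weight 1/size favours small clusters, which a plain
#' plurality of 30 neighbours could never award. The assigned cluster is
#' the argmax; ties go to the lower cluster id (logged). Confidence is the
#' winning cluster's share of the total weighted vote.
#'
#' @param new_genomes A [corpus()] of genomes to place.
#' @param model A `virtaxa_reference` from [fit_reference()].
#' @param k Number of neighbours, default 30 (must not exceed the model
#'   size).
#' @param weighting Function of cluster size giving the per-neighbour vote
#'   weight; default `function(s) 1 / s`.
#' @param min_confidence Optional threshold in (0, 1]; assignments below it
#'   get cluster `NA` (left unplaced).
#' @param exclude_self If `TRUE`, a query whose id is itself in the
#'   reference model is not allowed to vote for itself (used when
#'   re-classifying the reference genomes as a consistency check).
#' @return data.frame with one row per new genome: `genome_id`, `cluster`,
#'   `confidence`, `neighbor_ids` (comma-separated).
#' @export
knn_classify <- function(new_genomes, model, k = 30L,
                         weighting = function(s) 1 / s,
                         min_confidence = NULL, exclude_self = FALSE) {
  n_ref <- nrow(model$flags) - as.integer(isTRUE(exclude_self))
  if (k > n_ref) {
    stop("k = ", k, " exceeds the reference model size ", n_ref)
  }
  sizes <- model$cluster_sizes
  w_of_cluster <- setNames(vapply(as.numeric(sizes), weighting, 0),
                           names(sizes))
  out <- lapply(genome_ids(new_genomes), function(id) {
    g <- new_genomes$genomes[[id]]
    rep_g <- representation_flags(count_kmers(g$nt_sequence, model$k),
                                  model$baseline)
    d <- vi_to_reference(rep_g$flags, model$flags)
    if (exclude_self) d[rownames(model$flags) == id] <- Inf
    nn <- order(d)[seq_len(k)]
    nn_ids <- rownames(model$flags)[nn]
    nn_clusters <- model$labels[nn_ids]
    votes <- tapply(w_of_cluster[as.character(nn_clusters)],
                    nn_clusters, sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      message("tie between clusters ", paste(top, collapse = ", "),
              " for genome ", id, "; lower id wins")
    }
    win <- min(as.integer(top))
    conf <- max(votes) / sum(votes)
    data.frame(genome_id = id, cluster = win, confidence = conf,
               neighbor_ids = paste(nn_ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(min_confidence)) {
    res$cluster[res$confidence < min_confidence] <- NA_integer_
  }
  res
}

#' Serialize / load a reference model as JSON
#'
#' Flags are stored as 0/1 bitstrings, one per reference genome, so the
#' model is a single plain-text document.
#'
#' @param model A `virtaxa_reference`.
#' @param path JSON file.
#' @return `path` / the model.
#' @export
write_reference_model <- function(model, path) {
  doc <- list(
    k = model$k,
    baseline = as.numeric(model$baseline$frequencies),
    kmer_names = names(model$baseline$frequencies),
    total_tokens = model$baseline$total_tokens,
    ids = rownames(model$flags),
    flags = apply(model$flags, 1, function(f) {
      paste(as.integer(f), collapse = "")
    }),
    labels = as.integer(model$labels))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  flags <- do.call(rbind, lapply(doc$flags, function(s) {
    as.integer(strsplit(s, "")[[1]]) == 1L
  }))
  rownames(flags) <- doc$ids
  colnames(flags) <- doc$kmer_names
  labs <- setNames(as.integer(doc$labels), doc$ids)
  structure(list(
    baseline = list(frequencies = setNames(doc$baseline, doc$kmer_names),
                    total_tokens = doc$total_tokens),
    flags = flags, p_over = rowMeans(flags), labels = labs,
    cluster_sizes = table(labs), k = doc$k),
    class = "virtaxa_reference")
}
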