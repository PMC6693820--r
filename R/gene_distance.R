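#' Gene entropy from a score table
#'
#' The entropy of a gene is its self-alignment bit score: the mutual
#' information between the gene and itself.
#'
#' @param gene_id Gene id.
#' @param scores A `gene_score_table` ([align_corpus()] or
#'   [tabular_score_table()]).
#' @return Entropy in bits.
#' @export
gene_entropy <- function(gene_id, scores) {
  h <- unname(scores$entropy[gene_id])
  if (length(h) != 1 || is.na(h)) {
    stop("no self-alignment score for gene '", gene_id,
         "'; its entropy is undefined")
  }
  h
}

#' Variation of information between two genes
#'
#' VI = H(A) + H(B) - 2 I(A,B), with the mutual information I read off the
#' alignment bit score. Search heuristics can make I exceed the entropies
#' and drive VI negative; such values are raised to a small positive floor
#' `epsilon` so they cannot blow up the parallel (inverse-sum) combination.
#'
#' @param H_a,H_b Gene entropies in bits.
#' @param I Mutual information (alignment bit score) in bits.
#' @param epsilon Positive floor in bits (default `1e-6`).
#' @return VI in bits, always `>= epsilon`.
#' @export
gene_variation_of_information <- function(H_a, H_b, I, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  max(H_a + H_b - 2 * I, epsilon)
}

#' Parallel-resistor genome distance from per-gene distances
#'
#' The genome distance is the equivalent resistance of the per-gene
#' variations of information wired in parallel: 1 / sum(1 / D_i). Gene
#' pairs with no match are open circuits and contribute nothing; with no
#' matches at all the distance is undefined and the no-match sentinel
#' (`Inf`) is returned.
#'
#' @param gene_vis Numeric vector of per-gene-pair VIs (bits, all > 0).
#' @return List with `D_eq` (bits, or `Inf` when no matches) and
#'   `n_matches`.
#' @export
genome_pair_distance <- function(gene_vis) {
  if (length(gene_vis) == 0) return(list(D_eq = Inf, n_matches = 0L))
  stopifnot(all(gene_vis > 0))
  list(D_eq = 1 / sum(1 / gene_vis), n_matches = length(gene_vis))
}

#' Gene-alignment distance matrix for a corpus
#'
#' For every genome pair, all matched gene pairs between them contribute
#' their variation of information to the parallel sum; pairs of genomes
#' with no gene match get the no-match sentinel `Inf`. The diagonal is 0 by
#' convention. The number of VIs clamped at the `epsilon` floor is reported
#' via `attr(, "n_clamped")` and a message.
#'
#' @param corpus A [corpus()].
#' @param scores A `gene_score_table`; computed with [align_corpus()] when
#'   omitted.
#' @param epsilon VI floor in bits, see [gene_variation_of_information()].
#' @param params [aligner_params()] used when `scores` is omitted.
#' @return Symmetric numeric matrix (bits) with genome ids as dimnames,
#'   `Inf` sentinels allowed; attributes `n_clamped` and `n_matches`
#'   (matrix of contributing gene-pair counts).
#' @export
gene_distance_matrix <- function(corpus, scores = NULL, epsilon = 1e-6,
                                 params = aligner_params()) {
  if (is.null(scores)) scores <- align_corpus(corpus, params)
  ids <- genome_ids(corpus)
  n <- length(ids)
  genes <- corpus_genes(corpus)
  genome_of <- vapply(genes, `[[`, "", "genome_id")
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  nm <- matrix(0L, n, n, dimnames = list(ids, ids))
  hits <- scores$hits
  n_clamped <- 0L
  if (nrow(hits) > 0) {
    ga <- genome_of[hits$gene_a]
    gb <- genome_of[hits$gene_b]
    H_a <- vapply(hits$gene_a, gene_entropy, 0, scores = scores)
    H_b <- vapply(hits$gene_b, gene_entropy, 0, scores = scores)
    vi <- H_a + H_b - 2 * hits$bitscore
    n_clamped <- sum(vi < epsilon)
    vi <- pmax(vi, epsilon)
    key <- paste0(pmin(ga, gb), "\r", pmax(ga, gb))
    inv_sum <- tapply(1 / vi, key, sum)
    cnt <- tapply(vi, key, length)
    parts <- strsplit(names(inv_sum), "\r", fixed = TRUE)
    for (k in seq_along(inv_sum)) {
      i <- parts[[k]][1]; j <- parts[[k]][2]
      D[i, j] <- D[j, i] <- 1 / inv_sum[[k]]
      nm[i, j] <- nm[j, i] <- as.integer(cnt[[k]])
    }
  }
  if (n_clamped > 0) {
    message(n_clamped, " negative gene VI value(s) raised to epsilon = ",
            epsilon)
  }
  attr(D, "n_clamped") <- n_clamped
  attr(D, "n_matches") <- nm
  D
}

#' Write / read a distance matrix as TSV
#'
#' Header row and first column hold genome ids; the no-match sentinel is
#' serialized as `inf`.
#'
#' @param D Symmetric numeric matrix with dimnames.
#' @param path File path.
#' @return `path` / the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  out <- format(D, trim = TRUE, digits = 15)
  out[is.infinite(D)] <- "inf"
  df <- cbind(id = rownames(D), as.data.frame(out, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(M))
  vals[tolower(M) %in% c("inf", "infinity")] <- Inf
  D <- matrix(vals, nrow(M), ncol(M), dimnames = list(ids, colnames(M)))
  stopifnot(identical(rownames(D), colnames(D)))
  D
}
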