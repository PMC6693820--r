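#' Count k-mers in a nucleotide sequence
#'
#' All sliding windows of width `k` advanced by one base are counted (all
#' reading frames, single strand), so a genome of length L contributes
#' about L tokens, not L/k. Windows containing N are excluded.
#'
#' @param sequence Nucleotide string.
#' @param k Word size, default 4 (256 types over `{A,C,G,T}`).
#' @return List with `counts` (named integer vector of length `4^k`,
#'   lexicographic order) and `total`.
#' @export
count_kmers <- function(sequence, k = 4L) {
  stopifnot(k >= 1)
  sequence <- normalize_nt(sequence)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  list(counts = counts, total = sum(counts))
}

#' Pooled corpus baseline of k-mer frequencies
#'
#' The fraction of all k-mer tokens, across every genome in the corpus,
#' that each of the `4^k` types accounts for. This is the "average genetic
#' material" each genome's own frequencies are compared against.
#'
#' @param corpus A [corpus()].
#' @param k Word size, default 4.
#' @return List with `frequencies` (named numeric, sums to 1) and
#'   `total_tokens`.
#' @export
corpus_baseline <- function(corpus, k = 4L) {
  counts <- Reduce(`+`, lapply(corpus$genomes, function(g) {
    count_kmers(g$nt_sequence, k)$counts
  }))
  total <- sum(counts)
  if (total == 0) stop("corpus contains no countable k-mers")
  list(frequencies = counts / total, total_tokens = total)
}

#' Over/under-representation flags for a genome
#'
#' A k-mer is flagged over-represented when its frequency within the genome
#' strictly exceeds its pooled corpus frequency; exact ties count as
#' under-represented. `p_over` is the fraction of the `4^k` types flagged.
#'
#' @param counts Result of [count_kmers()] for the genome.
#' @param baseline Result of [corpus_baseline()].
#' @return List with `flags` (named logical vector, length `4^k`) and
#'   `p_over`.
#' @export
representation_flags <- function(counts, baseline) {
  if (counts$total == 0) {
    stop("genome has no countable k-mers; too short for the k-mer metric")
  }
  flags <- counts$counts / counts$total > baseline$frequencies
  list(flags = flags, p_over = mean(flags))
}

binary_entropy <- function(p) {
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

kmer_cell_probs <- function(flags_a, flags_b, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(flags_a), length(flags_a))
  c(oo = sum(weights[flags_a & flags_b]),
    ou = sum(weights[flags_a & !flags_b]),
    uo = sum(weights[!flags_a & flags_b]),
    uu = sum(weights[!flags_a & !flags_b]))
}

#' Mutual information between two k-mer representations
#'
#' The over/under flag of a uniformly drawn k-mer type is a binary random
#' variable per genome; their mutual information is the four-term sum
#' I = sum p(a,b) log2( p(a,b) / (p(a) p(b)) ) over the joint over/under
#' cells, in bits. Cells with zero probability contribute zero.
#'
#' @param rep_a,rep_b Results of [representation_flags()].
#' @param weights Optional per-type probability weights (default uniform
#'   `1/4^k` per type; pass the baseline frequencies for the token-weighted
#'   variant).
#' @return Mutual information in bits.
#' @export
kmer_mutual_information <- function(rep_a, rep_b, weights = NULL) {
  p <- kmer_cell_probs(rep_a$flags, rep_b$flags, weights)
  pa <- p["oo"] + p["ou"]; pb <- p["oo"] + p["uo"]
  marg <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / marg[nz]))
}

kmer_vi_pair <- function(rep_a, rep_b, weights = NULL) {
  p <- kmer_cell_probs(rep_a$flags, rep_b$flags, weights)
  pa <- p[["oo"]] + p[["ou"]]; pb <- p[["oo"]] + p[["uo"]]
  I <- kmer_mutual_information(rep_a, rep_b, weights)
  max(binary_entropy(pa) + binary_entropy(pb) - 2 * I, 0)
}

#' K-mer variation-of-information matrix for a corpus
#'
#' VI(a,b) = H(a) + H(b) - 2 I(a,b) over the binary over/under flags,
#' computed against the pooled corpus baseline. Every entry is finite and
#' lies in `[0, 2]` bits (two binary variables), so this matrix provides a
#' distance even between genomes that share no aligned gene.
#'
#' @param corpus A [corpus()].
#' @param k Word size, default 4.
#' @param weighting `"uniform"` (each of the `4^k` types weighs `1/4^k`;
#'   the default) or `"token"` (types weighted by their pooled baseline
#'   frequency).
#' @return Symmetric matrix, zero diagonal, genome ids as dimnames;
#'   attribute `representations` holds the per-genome flag lists and
#'   `baseline` the pooled baseline.
#' @export
kmer_vi_matrix <- function(corpus, k = 4L,
                           weighting = c("uniform", "token")) {
  weighting <- match.arg(weighting)
  base <- corpus_baseline(corpus, k)
  weights <- if (weighting == "token") base$frequencies else NULL
  reps <- lapply(corpus$genomes, function(g) {
    representation_flags(count_kmers(g$nt_sequence, k), base)
  })
  ids <- genome_ids(corpus)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- kmer_vi_pair(reps[[i]], reps[[j]], weights)
      }
    }
  }
  attr(D, "representations") <- reps
  attr(D, "baseline") <- base
  D
}

#' Write k-mer count / flag tables as TSV
#'
#' One row per genome, one column per k-mer type.
#'
#' @param corpus A [corpus()].
#' @param path Output file.
#' @param what `"counts"` or `"flags"`.
#' @param k Word size.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(corpus, path, what = c("counts", "flags"),
                             k = 4L) {
  what <- match.arg(what)
  rows <- lapply(corpus$genomes, function(g) count_kmers(g$nt_sequence, k))
  M <- do.call(rbind, lapply(rows, `[[`, "counts"))
  if (what == "flags") {
    base <- corpus_baseline(corpus, k)
    M <- do.call(rbind, lapply(rows, function(r) {
      as.integer(representation_flags(r, base)$flags)
    }))
    colnames(M) <- names(rows[[1]]$counts)
  }
  df <- cbind(id = genome_ids(corpus),
              as.data.frame(M, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
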