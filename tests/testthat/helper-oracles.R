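## Independent oracles used across tests. These deliberately share no code
## with the package implementation paths they check.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

## naive full-matrix Smith-Waterman with affine gaps (gap of length L costs
## open + L * extend), score only; quadratic space, no tricks
sw_oracle <- function(a, b, mat = blosum62, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - extend, H[i, j - 1] - open - extend)
      F[i, j] <- max(F[i - 1, j] - extend, H[i - 1, j] - open - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## bit conversion mirroring the package's stated contract
bits_oracle <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

## best translated bit score over all 36 frame pairs, built on the naive DP
gene_bits_oracle <- function(nt_a, nt_b) {
  fa <- translate_six_frames(nt_a)
  fb <- translate_six_frames(nt_b)
  best <- 0
  for (x in fa) for (y in fb) {
    s <- sw_oracle(x, y)
    if (s > best) best <- s
  }
  bits_oracle(best)
}

## mutual information of two binary flag vectors through the entropy route
## I = H(A) + H(B) - H(A,B), a different decomposition from the package's
## four-term sum
mi_entropy_oracle <- function(fa, fb) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(fa)
  pj <- c(sum(fa & fb), sum(fa & !fb), sum(!fa & fb), sum(!fa & !fb)) / n
  h(c(mean(fa), 1 - mean(fa))) + h(c(mean(fb), 1 - mean(fb))) - h(pj)
}

## plain DBSCAN (Ester et al.), used as the clustering oracle on blob data
dbscan_oracle <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  labels <- rep(NA_integer_, n)  # NA = unvisited, -1 = noise
  cl <- -1L
  for (p in seq_len(n)) {
    if (!is.na(labels[p])) next
    nb <- which(D[p, ] <= eps)
    if (length(nb) < min_pts) {
      labels[p] <- -1L
      next
    }
    cl <- cl + 1L
    labels[p] <- cl
    queue <- setdiff(nb, p)
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (!is.na(labels[q]) && labels[q] != -1L) next
      labels[q] <- cl
      nbq <- which(D[q, ] <= eps)
      if (length(nbq) >= min_pts) {
        queue <- c(queue, setdiff(nbq, which(!is.na(labels) & labels >= 0)))
      }
    }
  }
  labels
}

## random nucleotide / flag helpers
random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_flags <- function(n = 256, p = 0.5) {
  stats::runif(n) < p
}

## a tiny two-genome corpus sharing one near-identical gene
shared_gene_corpus <- function(seed = 1, rate = 0.02) {
  set.seed(seed)
  core <- random_nt(240)
  ga <- random_nt(600)
  gb <- random_nt(600)
  mk <- function(id, flank, shared) {
    seqs <- paste0(flank, shared)
    genome(id, seqs, genes = list(
      gene(paste0(id, "_shared"), id, shared, start = 600L,
           end = 600L + nchar(shared), strand = "+")))
  }
  corpus(list(mk("GA", ga, core),
              mk("GB", gb, mutate_sequence(core, rate))))
}

## adjusted Rand index via mclust (kept in one place so tests and the
## acceptance suite agree on the reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
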