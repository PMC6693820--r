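test_that("sliding-window 4-mer counting matches the worked example", {
  kc <- count_kmers("ACGACGA")
  expect_equal(unname(kc$counts["ACGA"]), 2)
  expect_equal(unname(kc$counts["CGAC"]), 1)
  expect_equal(unname(kc$counts["GACG"]), 1)
  expect_equal(kc$total, 4)
  expect_equal(sum(kc$counts > 0), 3L)
})

test_that("k-mer counting handles short sequences and N exclusion", {
  expect_equal(count_kmers("ACG")$total, 0)          # shorter than k
  expect_equal(count_kmers("ACGTNACGT")$total, 2)    # N windows excluded
  set.seed(51)
  for (i in 1:10) {
    s <- random_nt(50)
    one <- count_kmers(s)$counts
    two <- count_kmers(paste0(s, s))$counts
    expect_true(all(two >= 2 * one))                 # doubling plus junction
  }
})

test_that("the corpus baseline pools token counts over all genomes", {
  g1 <- genome("a", "ACGACGA")
  g2 <- genome("b", "TTTTTTT")
  base <- corpus_baseline(corpus(list(g1, g2)))
  expect_equal(sum(base$frequencies), 1)
  expect_equal(unname(base$frequencies["TTTT"]), 4 / 8)
  expect_equal(unname(base$frequencies["ACGA"]), 2 / 8)
  ## single-genome corpus: baseline is that genome's own spectrum
  solo <- corpus_baseline(corpus(list(g1)))
  expect_equal(unname(solo$frequencies["ACGA"]), 0.5)
  ## degenerate all-A corpus
  aaa <- corpus_baseline(corpus(list(genome("c", "AAAAAAAA"))))
  expect_equal(unname(aaa$frequencies["AAAA"]), 1)
  expect_equal(sum(aaa$frequencies), 1)
})

test_that("representation flags use strict excess, ties count as under", {
  g1 <- genome("a", "ACGACGA")
  crp <- corpus(list(g1))
  base <- corpus_baseline(crp)
  rep1 <- representation_flags(count_kmers(g1$nt_sequence), base)
  expect_false(any(rep1$flags))          # genome == corpus, all ties
  expect_equal(rep1$p_over, 0)
  ## pure-A genome against a mixed baseline: exactly AAAA is over
  g2 <- genome("b", paste(rep("A", 100), collapse = ""))
  base2 <- corpus_baseline(corpus(list(g1, g2)))
  rep2 <- representation_flags(count_kmers(g2$nt_sequence), base2)
  expect_identical(unname(which(rep2$flags)),
                   which(names(rep2$flags) == "AAAA"))
  expect_equal(rep2$p_over, 1 / 256)
  expect_error(representation_flags(count_kmers("ACG"), base), "too short")
})

test_that("flags match a brute-force recomputation from raw frequencies", {
  sim <- simulate_corpus(simulation_config(n_families = 2,
                                           genomes_per_family = 3,
                                           seed = 6))
  base <- corpus_baseline(sim$corpus)
  for (g in sim$corpus$genomes) {
    kc <- count_kmers(g$nt_sequence)
    rep_g <- representation_flags(kc, base)
    manual <- (kc$counts / sum(kc$counts)) > base$frequencies
    expect_identical(unname(rep_g$flags), unname(manual))
  }
})

test_that("binary mutual information matches closed forms and the entropy oracle", {
  f <- random_flags(256, 0.5)
  ra <- list(flags = f, p_over = mean(f))
  expect_equal(kmer_mutual_information(ra, ra),
               virtaxa:::binary_entropy(mean(f)))  # I(A,A) = H(A)
  ## independence: 128/128 marginals with a 64-cell overlap
  fa <- rep(c(TRUE, FALSE), each = 128)
  fb <- rep(rep(c(TRUE, FALSE), each = 64), 2)
  expect_equal(kmer_mutual_information(list(flags = fa), list(flags = fb)),
               0)
  ## 128/128 marginals, 96 shared over-representations
  fa <- rep(c(TRUE, FALSE), each = 128)
  fb <- c(rep(TRUE, 96), rep(FALSE, 32), rep(FALSE, 96), rep(TRUE, 32))
  I <- kmer_mutual_information(list(flags = fa), list(flags = fb))
  expect_equal(I, mi_entropy_oracle(fa, fb), tolerance = 1e-12)
  expect_equal(I, 0.18872, tolerance = 1e-4)
  ## and the corresponding VI
  expect_equal(virtaxa:::kmer_vi_pair(list(flags = fa), list(flags = fb)),
               2 - 2 * I, tolerance = 1e-12)
  ## random fixtures against the oracle
  set.seed(52)
  for (i in 1:50) {
    fa <- random_flags(256, runif(1, 0.1, 0.9))
    fb <- random_flags(256, runif(1, 0.1, 0.9))
    expect_equal(kmer_mutual_information(list(flags = fa), list(flags = fb)),
                 mi_entropy_oracle(fa, fb), tolerance = 1e-9)
  }
})

test_that("the k-mer VI matrix is a finite bounded distance on genomes", {
  sim <- simulate_corpus(simulation_config(n_families = 2,
                                           genomes_per_family = 4,
                                           seed = 7))
  K <- kmer_vi_matrix(sim$corpus)
  expect_true(all(is.finite(K)))
  expect_true(all(K >= 0 & K <= 2))
  expect_equal(as.vector(K), as.vector(t(K)))
  expect_equal(unname(diag(K)), rep(0, nrow(K)))
})

test_that("VI satisfies the metric axioms on random representations", {
  set.seed(53)
  reps <- lapply(1:20, function(i) list(flags = random_flags(256,
                                                             runif(1, .2, .8))))
  n <- length(reps)
  V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    V[i, j] <- virtaxa:::kmer_vi_pair(reps[[i]], reps[[j]])
  }
  expect_equal(unname(diag(V)), rep(0, n))              # identity
  expect_equal(V, t(V), tolerance = 1e-12)              # symmetry
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {        # triangle
    expect_lte(V[i, j], V[i, k] + V[k, j] + 1e-12)
  }
})

test_that("token-weighted probabilities are available as a variant", {
  sim <- simulate_corpus(simulation_config(n_families = 2,
                                           genomes_per_family = 3,
                                           seed = 8))
  Ku <- kmer_vi_matrix(sim$corpus, weighting = "uniform")
  Kt <- kmer_vi_matrix(sim$corpus, weighting = "token")
  expect_true(all(is.finite(Kt)))
  expect_true(all(Kt >= 0 & Kt <= 2 + 1e-12))
  expect_false(isTRUE(all.equal(Ku, Kt)))   # genuinely different measure
})
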