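#' Aligner parameters
#'
#' Scoring parameters for the built-in six-frame translated local aligner
#' and the raw-score-to-bits conversion. The Karlin–Altschul constants
#' `lambda` (nats per score unit) and `K` convert a raw Smith–Waterman score
#' S into a bit score S' = (lambda * S - ln K) / ln 2. Defaults are the
#' standard gapped BLOSUM62 values (gap open 11, extend 1). The absolute
#' scale of the bit score only sets the units of the gene distance matrix;
#' the k-mer rescaling step absorbs any overall factor.
#'
#' @param substitution_matrix_name Name of a matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Positive Karlin–Altschul constants.
#' @param min_bitscore Hits below this many bits are treated as no match,
#'   suppressing chance matches in the parallel sum. Default 50: the exact
#'   local aligner applies no e-value or database-size correction, so for
#'   genes of around a hundred codons the best-of-36-frame-pairs chance
#'   score already reaches the mid-20s in bits, while genuinely homologous
#'   genes score far higher.
#' @return An `aligner_params` list.
#' @export
aligner_params <- function(substitution_matrix_name = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, min_bitscore = 50) {
  stopifnot(lambda > 0, K > 0, gap_open > 0, gap_extend > 0,
            min_bitscore >= 0)
  structure(list(substitution_matrix_name = substitution_matrix_name,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, min_bitscore = min_bitscore),
            class = "aligner_params")
}

get_substitution_matrix <- function(params) {
  e <- new.env()
  utils::data(list = params$substitution_matrix_name,
              package = "Biostrings", envir = e)
  get(params$substitution_matrix_name, envir = e)
}

raw_to_bits <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames 1–3 read the sequence at offsets 0/1/2; frames 4–6 read the
#' reverse complement at the same offsets. Standard genetic code, stop
#' codons as `*`, trailing partial codons dropped, ambiguous codons as `X`.
#'
#' @param nt_sequence Nucleotide string, length >= 3.
#' @return Character vector of 6 amino-acid strings (possibly empty for
#'   frames that retain no full codon).
#' @export
translate_six_frames <- function(nt_sequence) {
  nt_sequence <- normalize_nt(nt_sequence)
  n <- nchar(nt_sequence)
  if (n < 3) stop("sequence shorter than one codon")
  strands <- c(nt_sequence, reverse_complement_nt(nt_sequence))
  out <- character(6)
  for (s in 1:2) {
    for (off in 0:2) {
      len <- ((n - off) %/% 3) * 3
      out[(s - 1) * 3 + off + 1] <- if (len < 3) "" else {
        as.character(Biostrings::translate(
          Biostrings::DNAString(substr(strands[s], off + 1, off + len)),
          if.fuzzy.codon = "solve"))
      }
    }
  }
  out
}

## best raw Smith-Waterman score over all frame combinations, per gene pair
sw_pair_scores <- function(frames, pairs, mat, params) {
  .sw_best_pair_scores(frames, pairs, mat, rownames(mat),
                       params$gap_open, params$gap_extend)
}

#' Translated local alignment bit score between two genes
#'
#' Best Smith–Waterman local alignment raw score over all 36 pairs of
#' reading frames of the two genes, converted to bits via the
#' Karlin–Altschul constants in `params`. This is the desk-scale stand-in
#' for an external translated search: exact local dynamic programming, no
#' seeding heuristics.
#'
#' @param gene_a,gene_b [gene()] objects (or plain nucleotide strings).
#' @param params [aligner_params()].
#' @return Bit score (numeric), or `NA_real_` for no match (score below
#'   `params$min_bitscore`, or a gene shorter than one codon).
#' @export
local_align_bitscore <- function(gene_a, gene_b, params = aligner_params()) {
  sa <- if (is.character(gene_a)) gene_a else gene_a$nt_sequence
  sb <- if (is.character(gene_b)) gene_b else gene_b$nt_sequence
  if (nchar(sa) < 3 || nchar(sb) < 3) return(NA_real_)
  mat <- get_substitution_matrix(params)
  best <- sw_pair_scores(list(translate_six_frames(sa),
                              translate_six_frames(sb)),
                         matrix(1:2, 1), mat, params)
  bits <- raw_to_bits(best, params)
  if (best <= 0 || bits < params$min_bitscore) NA_real_ else bits
}

#' All-pairs gene bit scores for a corpus (internal aligner)
#'
#' Computes, for every pair of genes belonging to different genomes, the
#' best translated local alignment bit score, and for every gene its
#' self-alignment bit score (the gene's entropy). Scores below
#' `params$min_bitscore` are dropped.
#'
#' @param corpus A [corpus()].
#' @param params [aligner_params()].
#' @return A `gene_score_table`: list with `entropy` (named numeric, bits
#'   per gene id) and `hits` (data.frame `gene_a`, `gene_b`, `bitscore`
#'   with `gene_a` < `gene_b` lexicographic, one row per matched unordered
#'   pair).
#' @export
align_corpus <- function(corpus, params = aligner_params()) {
  genes <- corpus_genes(corpus)
  ids <- names(genes)
  ng <- length(genes)
  mat <- get_substitution_matrix(params)
  frames <- lapply(genes, function(g) {
    if (nchar(g$nt_sequence) < 3) character(0)
    else translate_six_frames(g$nt_sequence)
  })
  genome_of <- vapply(genes, `[[`, "", "genome_id")
  has_frames <- vapply(frames, length, 0L) > 0

  entropy <- rep(NA_real_, ng)
  names(entropy) <- ids
  if (any(has_frames)) {
    self_idx <- which(has_frames)
    raw_self <- sw_pair_scores(frames, cbind(self_idx, self_idx), mat,
                               params)
    entropy[self_idx] <- raw_to_bits(raw_self, params)
  }

  hits <- data.frame(gene_a = character(0), gene_b = character(0),
                     bitscore = numeric(0), stringsAsFactors = FALSE)
  if (ng >= 2) {
    pr <- which(upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
    pr <- pr[genome_of[pr[, 1]] != genome_of[pr[, 2]] &
             has_frames[pr[, 1]] & has_frames[pr[, 2]], , drop = FALSE]
    if (nrow(pr) > 0) {
      raw <- sw_pair_scores(frames, pr, mat, params)
      bits <- raw_to_bits(raw, params)
      keep <- raw > 0 & bits >= params$min_bitscore
      if (any(keep)) {
        ka <- ids[pr[keep, 1]]; kb <- ids[pr[keep, 2]]
        swap <- ka > kb
        hits <- data.frame(gene_a = ifelse(swap, kb, ka),
                           gene_b = ifelse(swap, ka, kb),
                           bitscore = bits[keep], stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(entropy = entropy, hits = hits),
            class = "gene_score_table")
}

#' Parse 12-column tabular search hits
#'
#' Reads the common 12-column tab-separated hit format (query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score) produced by external
#' translated-search tools run on the FASTA written by
#' [write_gene_fasta()]. Sequence ids may be either bare gene ids or
#' `genomeid|geneid`.
#'
#' Self-hits (query == subject) provide gene entropies; hits between
#' different genes of the same genome are discarded; for each remaining
#' ordered pair only the maximum bit score is retained.
#'
#' @param path Tabular hit file.
#' @param corpus The [corpus()] whose genes the ids must resolve in.
#' @return A list with `matches` (data.frame `gene_a`, `gene_b`,
#'   `bitscore`, one row per retained ordered-pair hit) and `self` (named
#'   numeric of self-hit bit scores).
#' @export
parse_tabular_hits <- function(path, corpus) {
  genes <- corpus_genes(corpus)
  genome_of <- vapply(genes, `[[`, "", "genome_id")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  qa <- character(0); qb <- character(0); sc <- numeric(0)
  self <- numeric(0)
  strip_id <- function(x) sub("^[^|]*\\|", "", x)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12) {
      stop("malformed hit line ", i, ": expected 12 tab-separated columns, ",
           "got ", length(f))
    }
    bits <- suppressWarnings(as.numeric(f[12]))
    if (is.na(bits) || bits < 0) {
      stop("malformed hit line ", i, ": bad bitscore '", f[12], "'")
    }
    a <- strip_id(f[1]); b <- strip_id(f[2])
    if (!a %in% names(genes) || !b %in% names(genes)) {
      warning("hit line ", i, ": unknown gene id '",
              if (!a %in% names(genes)) a else b, "', skipped",
              call. = FALSE)
      next
    }
    if (a == b) {
      self[a] <- max(self[a], bits, na.rm = TRUE)
    } else if (genome_of[a] == genome_of[b]) {
      next  # intra-genome hit: Eq-style parallel sum is inter-genome only
    } else {
      qa <- c(qa, a); qb <- c(qb, b); sc <- c(sc, bits)
    }
  }
  list(matches = data.frame(gene_a = qa, gene_b = qb, bitscore = sc,
                            stringsAsFactors = FALSE),
       self = self)
}

#' Symmetrize hits into a best-score table per unordered gene pair
#'
#' For each unordered gene pair the maximum bit score over both orderings
#' and all hits is retained; the result is independent of input order.
#'
#' @param matches data.frame `gene_a`, `gene_b`, `bitscore` (ordered pairs
#'   allowed in either or both directions, duplicates allowed).
#' @return data.frame `gene_a`, `gene_b`, `bitscore` with `gene_a` <
#'   `gene_b` and one row per pair.
#' @export
best_hit_table <- function(matches) {
  if (nrow(matches) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  a <- pmin(matches$gene_a, matches$gene_b)
  b <- pmax(matches$gene_a, matches$gene_b)
  key <- paste0(a, "\r", b)
  best <- tapply(matches$bitscore, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[[`, "", 1),
                    gene_b = vapply(parts, `[[`, "", 2),
                    bitscore = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a gene score table from parsed tabular hits
#'
#' Counterpart of [align_corpus()] for externally computed alignments.
#'
#' @param hits Result of [parse_tabular_hits()].
#' @param corpus The corpus (used to check self-score coverage lazily; a
#'   gene with matches but no self-hit raises an error in
#'   [gene_distance_matrix()]).
#' @return A `gene_score_table`.
#' @export
tabular_score_table <- function(hits, corpus) {
  genes <- corpus_genes(corpus)
  entropy <- setNames(rep(NA_real_, length(genes)), names(genes))
  entropy[names(hits$self)] <- hits$self
  structure(list(entropy = entropy, hits = best_hit_table(hits$matches)),
            class = "gene_score_table")
}
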