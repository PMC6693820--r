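#' @importFrom stats dist runif setNames hclust as.dist
#' @importFrom utils read.table write.table packageVersion tail
#' @importFrom Rcpp evalCpp
#' @useDynLib virtaxa, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

## normalize a nucleotide string: uppercase, IUPAC ambiguity codes -> N.
## The k-mer alphabet is {A,C,G,T}; windows containing N are never counted,
## so collapsing all ambiguity codes to N is lossless for every metric here.
normalize_nt <- function(x, warn_context = NULL) {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    if (!is.null(warn_context)) {
      warning(sprintf("non-ACGTN characters in %s mapped to N", warn_context),
              call. = FALSE)
    }
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

#' Create a gene
#'
#' A gene is a coding sequence extracted from a genome, stored in coding
#' orientation (minus-strand genes are reverse-complemented on extraction).
#' Coordinates are 0-based half-open on the parent genome.
#'
#' @param id Gene identifier, unique within a corpus.
#' @param genome_id Identifier of the parent genome.
#' @param nt_sequence Nucleotide string over `{A,C,G,T,N}` (coding strand).
#' @param start,end 0-based half-open location on the genome.
#' @param strand `"+"` or `"-"`.
#' @return A `virtaxa_gene` object.
#' @export
gene <- function(id, genome_id, nt_sequence, start, end, strand = "+") {
  nt_sequence <- normalize_nt(nt_sequence)
  stopifnot(nzchar(nt_sequence), end > start,
            nchar(nt_sequence) == end - start,
            strand %in% c("+", "-"))
  structure(list(id = as.character(id), genome_id = as.character(genome_id),
                 nt_sequence = nt_sequence, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "virtaxa_gene")
}

#' Create a genome
#'
#' A genome is a nucleotide sequence together with its annotated genes
#' (possibly none) and optional metadata labels. Metadata (host, Baltimore
#' class, ICTV family) are carried for reporting only and never enter any
#' computation.
#'
#' @param id Accession / identifier.
#' @param nt_sequence Nucleotide string over `{A,C,G,T,N}`.
#' @param genes List of [gene()] objects located on this genome.
#' @param name Human-readable name (defaults to `id`).
#' @param metadata Optional named list of labels.
#' @return A `virtaxa_genome` object.
#' @export
genome <- function(id, nt_sequence, genes = list(), name = id,
                   metadata = list()) {
  nt_sequence <- normalize_nt(nt_sequence)
  n <- nchar(nt_sequence)
  gids <- vapply(genes, `[[`, "", "id")
  stopifnot(!anyDuplicated(gids))
  for (g in genes) {
    stopifnot(g$start >= 0L, g$end <= n)
  }
  structure(list(id = as.character(id), name = name,
                 nt_sequence = nt_sequence,
                 genes = setNames(genes, gids), metadata = metadata),
            class = "virtaxa_genome")
}

#' Create a corpus of genomes
#'
#' The order of genomes is stable and defines the row/column order of every
#' distance matrix computed from the corpus.
#'
#' @param genomes List of [genome()] objects with unique ids.
#' @return A `virtaxa_corpus` object.
#' @export
corpus <- function(genomes) {
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(genomes = setNames(genomes, ids)), class = "virtaxa_corpus")
}

#' @export
length.virtaxa_corpus <- function(x) length(x$genomes)

#' @export
print.virtaxa_corpus <- function(x, ...) {
  ng <- sum(vapply(x$genomes, function(g) length(g$genes), 0L))
  cat(sprintf("<virtaxa corpus: %d genomes, %d genes>\n", length(x), ng))
  invisible(x)
}

#' Genome ids of a corpus, in matrix order
#' @param x A corpus.
#' @return Character vector of genome ids.
#' @export
genome_ids <- function(x) names(x$genomes)

#' All genes of a corpus as a flat named list
#'
#' Names are gene ids; order follows genome order then gene order.
#' @param x A corpus.
#' @return Named list of `virtaxa_gene` objects.
#' @export
corpus_genes <- function(x) {
  gs <- unlist(lapply(x$genomes, `[[`, "genes"), recursive = FALSE,
               use.names = FALSE)
  if (length(gs) == 0) return(list())
  ids <- vapply(gs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("gene ids are not unique within the corpus")
  setNames(gs, ids)
}

reverse_complement_nt <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a nucleotide FASTA file as a corpus
#'
#' Each record becomes one genome with an empty gene list (so only the k-mer
#' metric applies to it). The header token before the first whitespace is
#' the genome id.
#'
#' @param path FASTA file.
#' @return A [corpus()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  full_names <- names(seqs)
  ids <- vapply(strsplit(full_names, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genomes <- lapply(seq_along(seqs), function(i) {
    genome(ids[i], normalize_nt(as.character(seqs[[i]]), warn_context = ids[i]),
           name = full_names[i])
  })
  corpus(genomes)
}

#' Write a corpus as a nucleotide FASTA file
#' @param x A corpus.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(x$genomes, `[[`, "", "nt_sequence"))
  names(seqs) <- genome_ids(x)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write the extracted genes of a corpus as FASTA
#'
#' One record per gene, id `genomeid|geneid`, in coding orientation — the
#' input expected by external translated-search tools whose tabular output
#' [parse_tabular_hits()] ingests.
#'
#' @param x A corpus.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(x, path) {
  genes <- corpus_genes(x)
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "nt_sequence"))
  names(seqs) <- vapply(genes, function(g) paste0(g$genome_id, "|", g$id), "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Merge genomes that share an organism name
#'
#' Opt-in handling for multi-segment viruses: records whose `organism`
#' metadata matches are concatenated into a single genome (sequences joined,
#' genes pooled with coordinates shifted). Off by default because segment
#' bookkeeping varies between databases.
#'
#' @param x A corpus whose genomes carry an `organism` metadata entry.
#' @return A corpus with one genome per organism.
#' @export
merge_segments <- function(x) {
  org <- vapply(x$genomes, function(g) {
    o <- g$metadata$organism
    if (is.null(o)) g$id else o
  }, "")
  merged <- lapply(split(x$genomes, org), function(gs) {
    if (length(gs) == 1) return(gs[[1]])
    seqs <- vapply(gs, `[[`, "", "nt_sequence")
    offs <- unname(cumsum(c(0L, nchar(seqs)[-length(seqs)])))
    genes <- list()
    for (i in seq_along(gs)) {
      for (g in gs[[i]]$genes) {
        g$start <- g$start + offs[i]
        g$end <- g$end + offs[i]
        g$genome_id <- gs[[1]]$id
        genes[[length(genes) + 1L]] <- g
      }
    }
    genome(gs[[1]]$id, paste(seqs, collapse = ""), genes = genes,
           name = gs[[1]]$name, metadata = gs[[1]]$metadata)
  })
  ## preserve first-appearance order
  first <- vapply(split(seq_along(org), org), min, 0)
  corpus(unname(merged[order(first[names(merged)])]))
}
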