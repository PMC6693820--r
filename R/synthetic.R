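#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure the genome distance relies on: a
#' corpus of families, each descending from an ancestor genome of several
#' protein-coding genes separated by intergenic spacers. Within a family,
#' descendants diverge by per-site nucleotide substitution plus whole-gene
#' loss and gain, so translated alignment finds gene matches; across
#' families sequences are unrelated and only the 4-mer signal (driven
#' partly by each family's GC bias) remains — mirroring the regime split
#' between the gene-alignment and k-mer metrics.
#'
#' @param n_families Number of families (default 3).
#' @param genomes_per_family Descendants per family (default 10).
#' @param genes_per_ancestor Integer range, genes per ancestor (default
#'   4:6).
#' @param gene_length Range of gene lengths in codons (default 60:120).
#' @param intergenic_length Range of intergenic region lengths in bases
#'   (default 150:400, the scale of viral UTRs). Intergenic regions belong
#'   to the ancestor and are inherited and mutated by descendants, as real
#'   non-coding regions are.
#' @param substitution_rate Per-site substitution probability per
#'   descendant (default 0.05).
#' @param gene_loss_prob,gene_gain_prob Per-gene loss / per-genome gain
#'   probabilities (default 0.1 each).
#' @param gc_bias Numeric vector of per-family GC fractions in (0, 1);
#'   default evenly spaced in \[0.35, 0.65\].
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the config.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_families = 3L, genomes_per_family = 10L,
                              genes_per_ancestor = 4:6,
                              gene_length = 60:120,
                              intergenic_length = 150:400,
                              substitution_rate = 0.05,
                              gene_loss_prob = 0.1, gene_gain_prob = 0.1,
                              gc_bias = NULL, seed = 1L) {
  if (is.null(gc_bias)) {
    gc_bias <- if (n_families == 1) 0.5 else
      seq(0.35, 0.65, length.out = n_families)
  }
  stopifnot(n_families >= 1, genomes_per_family >= 1,
            length(gc_bias) == n_families, all(gc_bias > 0 & gc_bias < 1),
            substitution_rate >= 0, substitution_rate <= 1,
            gene_loss_prob >= 0, gene_loss_prob <= 1,
              gene_gain_prob >= 0, gene_gain_prob <= 1,
            length(genes_per_ancestor) >= 1, length(gene_length) >= 1,
            length(intergenic_length) >= 1)
  structure(list(n_families = n_families,
                 genomes_per_family = genomes_per_family,
                 genes_per_ancestor = genes_per_ancestor,
                 gene_length = gene_length,
                 intergenic_length = intergenic_length,
                 substitution_rate = substitution_rate,
                 gene_loss_prob = gene_loss_prob,
                 gene_gain_prob = gene_gain_prob,
                 gc_bias = gc_bias, seed = as.integer(seed)),
            class = "sim_config")
}

random_sequence <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
}

## a random protein-coding gene: ATG start, no in-frame stop, stop at end
random_gene_sequence <- function(n_codons, gc) {
  stopifnot(n_codons >= 3)
  body <- character(n_codons - 2L)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(body)) {
    repeat {
      cd <- random_sequence(3L, gc)
      if (!cd %in% stops) break
    }
    body[i] <- cd
  }
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
}

sample_range <- function(rng) if (length(rng) == 1) rng else sample(rng, 1)

#' Substitute bases of a sequence at a fixed per-site rate
#'
#' Each site is substituted independently with probability `rate`, to a
#' base drawn uniformly from the three alternatives. No indels.
#'
#' @param sequence Nucleotide string.
#' @param rate Per-site substitution probability in \[0, 1\].
#' @return Mutated nucleotide string of the same length.
#' @export
mutate_sequence <- function(sequence, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || !nzchar(sequence)) return(sequence)
  bases <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(bases)) < rate & bases %in% DNA_BASES)
  for (i in hit) {
    bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1)
  }
  paste(bases, collapse = "")
}

## lay out alternating spacer/gene elements into a genome with coordinates
assemble_genome <- function(id, name, gene_seqs, gene_ids, strands, spacers,
                            family) {
  pieces <- character(0)
  genes <- list()
  pos <- 0L
  for (i in seq_along(gene_seqs)) {
    pieces <- c(pieces, spacers[[i]])
    pos <- pos + nchar(spacers[[i]])
    coding <- gene_seqs[[i]]
    on_genome <- if (strands[i] == "-") reverse_complement_nt(coding) else
      coding
    pieces <- c(pieces, on_genome)
    genes[[i]] <- gene(gene_ids[i], id, coding, start = pos,
                       end = pos + nchar(on_genome), strand = strands[i])
    pos <- pos + nchar(on_genome)
  }
  pieces <- c(pieces, spacers[[length(spacers)]])
  genome(id, paste(pieces, collapse = ""), genes = genes, name = name,
         metadata = list(family = family))
}

#' Simulate a corpus of genomes with known family structure
#'
#' See [simulation_config()] for the generative model. Gene gain draws
#' novel random genes rather than transferring genes between families, so
#' families stay separable by construction; descendants of one family can
#' nevertheless end up sharing no single common gene, the regime the
#' parallel-resistor distance is designed to handle.
#'
#' @param config A [simulation_config()].
#' @return List with `corpus` (a [corpus()], CDS annotations included) and
#'   `families` (named integer vector of true family labels, 0-based).
#' @export
simulate_corpus <- function(config = simulation_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  genomes <- list()
  families <- integer(0)
  gene_counter <- 0L
  for (f in seq_len(config$n_families)) {
    gc <- config$gc_bias[f]
    n_genes <- sample_range(config$genes_per_ancestor)
    anc_seqs <- lapply(seq_len(n_genes), function(i) {
      random_gene_sequence(sample_range(config$gene_length), gc)
    })
    ## intergenic regions are part of the ancestor too (UTRs, packaging
    ## signals): descendants inherit and mutate them like genes
    anc_spacers <- lapply(seq_len(n_genes + 1L), function(i) {
      random_sequence(sample_range(config$intergenic_length), gc)
    })
    anc_strands <- sample(c("+", "-"), n_genes, replace = TRUE,
                          prob = c(0.8, 0.2))
    for (d in seq_len(config$genomes_per_family)) {
      seqs <- anc_seqs
      strands <- anc_strands
      spacers <- anc_spacers
      ids <- sprintf("F%dG%d", f, seq_len(n_genes))
      keep <- runif(length(seqs)) >= config$gene_loss_prob
      if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
      ## a lost gene takes its upstream spacer with it
      seqs <- seqs[keep]; strands <- strands[keep]; ids <- ids[keep]
      spacers <- spacers[c(keep, TRUE)]
      if (runif(1) < config$gene_gain_prob) {
        gene_counter <- gene_counter + 1L
        seqs <- c(seqs, random_gene_sequence(
          sample_range(config$gene_length), gc))
        strands <- c(strands, sample(c("+", "-"), 1, prob = c(0.8, 0.2)))
        ids <- c(ids, sprintf("NOV%d", gene_counter))
        spacers <- c(spacers[-length(spacers)],
                     random_sequence(sample_range(config$intergenic_length),
                                     gc),
                     spacers[length(spacers)])
      }
      seqs <- lapply(seqs, mutate_sequence, rate = config$substitution_rate)
      spacers <- lapply(spacers, mutate_sequence,
                        rate = config$substitution_rate)
      gid <- sprintf("FAM%02d_%02d", f, d)
      ids <- sprintf("%s_%s", gid, ids)
      genomes[[length(genomes) + 1L]] <- assemble_genome(
        gid, sprintf("synthetic virus, family %d, descendant %d", f, d),
        seqs, ids, strands, spacers, f - 1L)
      families[gid] <- f - 1L
    }
  }
  list(corpus = corpus(genomes), families = families)
}

#' Write true family labels as TSV
#' @param families Named integer vector from [simulate_corpus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_family_labels <- function(families, path) {
  write.table(data.frame(id = names(families), family = families),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
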