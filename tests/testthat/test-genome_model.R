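test_that("gene and genome constructors enforce their invariants", {
  g <- gene("g1", "G", "ATGAAA", 0, 6)
  expect_s3_class(g, "virtaxa_gene")
  expect_error(gene("g1", "G", "ATG", 0, 6))       # length != end - start
  expect_error(gene("g1", "G", "", 0, 0))          # empty
  expect_error(genome("G", "ATGAAA", genes = list(
    gene("g1", "G", "ATGAAAT", 0, 7))))            # gene beyond bounds
  expect_error(genome("G", "ATGAAA", genes = list(g, g)))  # duplicate ids
  expect_error(corpus(list(genome("A", "ACGT"), genome("A", "ACGT"))))
})

test_that("GenBank records map to genomes with one gene per CDS", {
  gb <- c(
    "LOCUS       REC1 60 bp    DNA     linear   VRL",
    "DEFINITION  three-gene record",
    "ACCESSION   REC1",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..9",
    '                     /locus_tag="a"',
    "     CDS             13..21",
    '                     /locus_tag="b"',
    "     CDS             31..42",
    '                     /locus_tag="c"',
    "ORIGIN",
    "        1 atgaaatgaa aatggcccta aaaaaaaaaa tggggcccaa atagaaaaaa",
    "       51 aaaaaaaaaa",
    "//",
    "LOCUS       REC2 12 bp    DNA     linear   VRL",
    "ACCESSION   REC2",
    "FEATURES             Location/Qualifiers",
    "     source          1..12",
    "ORIGIN",
    "        1 acgtacgtac gt",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  crp <- read_genbank(path)
  expect_equal(length(crp), 2L)
  expect_equal(length(crp$genomes[["REC1"]]$genes), 3L)
  expect_equal(length(crp$genomes[["REC2"]]$genes), 0L)
  expect_equal(crp$genomes[["REC1"]]$genes[["a"]]$nt_sequence, "ATGAAATGA")
  ## a record without CDS still feeds the k-mer metric
  expect_equal(count_kmers(crp$genomes[["REC2"]]$nt_sequence)$total, 9)
})

test_that("minus-strand CDS are extracted as the reverse complement", {
  ## bases 11..19 (1-based) are CATGCATGC; hand reverse complement
  seq30 <- "AAAAAAAAAACATGCATGCAAAAAAAAAAA"
  gb <- c(
    "LOCUS       MINUS 30 bp    DNA     linear   VRL",
    "ACCESSION   MINUS",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(11..19)",
    '                     /locus_tag="neg"',
    "ORIGIN",
    paste("        1", tolower(seq30)),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  crp <- read_genbank(path)
  gn <- crp$genomes[["MINUS"]]$genes[["neg"]]
  expect_equal(gn$nt_sequence, "GCATGCATG")
  expect_equal(gn$strand, "-")
  expect_equal(c(gn$start, gn$end), c(10L, 19L))
})

test_that("out-of-bounds CDS are skipped with a warning, bad files error", {
  gb <- c(
    "LOCUS       BAD 12 bp    DNA     linear   VRL",
    "ACCESSION   BAD",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    "ORIGIN",
    "        1 acgtacgtac gt",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(crp <- read_genbank(path), "outside sequence bounds")
  expect_equal(length(crp$genomes[["BAD"]]$genes), 0L)
  path2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not", "a", "genbank file"), path2)
  expect_error(read_genbank(path2), "GenBank")
})

test_that("FASTA corpora round-trip and are normalized on load", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">v1 first virus", "acgtacgt", ">v2", "GGGGCCCC"), path)
  crp <- read_fasta(path)
  expect_equal(genome_ids(crp), c("v1", "v2"))
  expect_equal(crp$genomes[["v1"]]$nt_sequence, "ACGTACGT")  # uppercased
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(crp, out)
  crp2 <- read_fasta(out)
  expect_identical(genome_ids(crp2), genome_ids(crp))
  expect_identical(vapply(crp2$genomes, `[[`, "", "nt_sequence"),
                   vapply(crp$genomes, `[[`, "", "nt_sequence"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT", ">x", "ACGT"), bad)
  expect_error(read_fasta(bad), "duplicate")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
})

test_that("ambiguity codes collapse to N with a warning", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">amb", "ACGTRYSWacgt"), path)
  expect_warning(crp <- read_fasta(path), "mapped to N")
  expect_equal(crp$genomes[["amb"]]$nt_sequence, "ACGTNNNNACGT")
})

test_that("reading the same file twice yields identical corpora", {
  sim <- simulate_corpus(simulation_config(n_families = 1,
                                           genomes_per_family = 2,
                                           seed = 5))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$corpus, path)
  c1 <- read_genbank(path)
  c2 <- read_genbank(path)
  expect_identical(c1, c2)
  ## and the GenBank writer/reader preserve genes and sequences exactly
  orig <- sim$corpus$genomes[[1]]
  back <- c1$genomes[[orig$id]]
  expect_identical(back$nt_sequence, orig$nt_sequence)
  expect_identical(vapply(back$genes, `[[`, "", "nt_sequence"),
                   vapply(orig$genes, `[[`, "", "nt_sequence"))
})

test_that("segment merging concatenates sequences and shifts genes", {
  g1 <- genome("S1", "AAACCC", genes = list(gene("x", "S1", "CCC", 3, 6)),
               metadata = list(organism = "Virus X"))
  g2 <- genome("S2", "GGGTTT", genes = list(gene("y", "S2", "GGG", 0, 3)),
               metadata = list(organism = "Virus X"))
  g3 <- genome("S3", "ACGT", metadata = list(organism = "Virus Y"))
  merged <- merge_segments(corpus(list(g1, g2, g3)))
  expect_equal(length(merged), 2L)
  m <- merged$genomes[["S1"]]
  expect_equal(m$nt_sequence, "AAACCCGGGTTT")
  expect_equal(m$genes[["y"]]$start, 6L)
  expect_equal(m$genes[["y"]]$nt_sequence, "GGG")
})
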