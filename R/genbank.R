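## Minimal GenBank flat-file reader/writer.
##
## Only the pieces of the format this pipeline consumes are supported: one
## genome per record, the ORIGIN sequence, and CDS features with plain,
## complement() and join() locations. Partial-end markers (< >) are
## stripped. Every CDS is extracted in coding orientation.

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  ivs <- t(vapply(seq_along(parts), function(i) {
    if (length(m[[i]]) == 3) as.integer(m[[i]][2:3])
    else if (length(single[[i]]) == 2) rep(as.integer(single[[i]][2]), 2)
    else stop("cannot parse location segment: ", parts[i])
  }, integer(2)))
  list(intervals = ivs, strand = strand)  # 1-based inclusive
}

extract_cds_sequence <- function(nt, intervals, strand) {
  seg <- vapply(seq_len(nrow(intervals)), function(i) {
    substr(nt, intervals[i, 1], intervals[i, 2])
  }, "")
  s <- paste(seg, collapse = "")
  if (strand == "-") s <- reverse_complement_nt(s)
  s
}

#' Read a GenBank flat file as a corpus
#'
#' One genome per record; one gene per CDS feature, extracted in coding
#' orientation (minus-strand CDS are reverse-complemented). Records without
#' CDS features yield genomes with empty gene lists, still usable by the
#' k-mer metric. GenBank 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GenBank flat file (one or more records).
#' @param merge_by_organism If `TRUE`, records sharing an ORGANISM line are
#'   merged into one genome (see [merge_segments()]). Default `FALSE`.
#' @return A [corpus()].
#' @export
read_genbank <- function(path, merge_by_organism = FALSE) {
  lines <- readLines(path)
  rec_start <- grep("^LOCUS ", lines)
  if (length(rec_start) == 0) stop("not a GenBank flat file: ", path)
  rec_end <- grep("^//", lines)
  if (length(rec_end) < length(rec_start)) {
    stop("GenBank record starting at line ", rec_start[length(rec_end) + 1],
         " is not terminated by //")
  }
  genomes <- lapply(seq_along(rec_start), function(r) {
    parse_gb_record(lines[rec_start[r]:rec_end[r]], path)
  })
  out <- corpus(genomes)
  if (merge_by_organism) merge_segments(out) else out
}

parse_gb_record <- function(rl, path) {
  locus_name <- strsplit(trimws(sub("^LOCUS", "", rl[1])), "\\s+")[[1]][1]
  if (is.na(locus_name) || !nzchar(locus_name)) {
    stop("malformed LOCUS line in ", path)
  }
  acc_line <- grep("^ACCESSION", rl, value = TRUE)
  id <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else locus_name
  if (is.na(id) || !nzchar(id)) id <- locus_name
  def_line <- grep("^DEFINITION", rl, value = TRUE)
  name <- if (length(def_line)) {
    trimws(sub("^DEFINITION", "", def_line[1]))
  } else id
  org_line <- grep("^\\s+ORGANISM", rl, value = TRUE)
  organism <- if (length(org_line)) {
    trimws(sub("^\\s+ORGANISM", "", org_line[1]))
  } else NULL

  origin <- grep("^ORIGIN", rl)
  if (length(origin) == 0) {
    stop("record ", id, " in ", path, " has no ORIGIN section")
  }
  seq_lines <- rl[(origin[1] + 1):(length(rl) - 1)]
  nt <- normalize_nt(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")),
                     warn_context = id)
  if (!nzchar(nt)) stop("record ", id, " in ", path, " has an empty sequence")

  ## collect CDS features: a feature key sits at column 6; its location may
  ## continue on following lines until the first /qualifier line
  feat0 <- grep("^FEATURES", rl)
  genes <- list()
  if (length(feat0)) {
    body <- rl[(feat0[1] + 1):(origin[1] - 1)]
    keys <- grepl("^     \\S", body)
    starts <- which(keys & grepl("^     CDS\\s", body))
    n_cds <- 0L
    for (s in starts) {
      loc <- trimws(sub("^     CDS", "", body[s]))
      j <- s + 1L
      while (j <= length(body) && !keys[j] &&
             !grepl("^\\s+/", body[j])) {
        loc <- paste0(loc, trimws(body[j]))
        j <- j + 1L
      }
      quals <- character(0)
      while (j <= length(body) && !keys[j]) {
        quals <- c(quals, trimws(body[j]))
        j <- j + 1L
      }
      n_cds <- n_cds + 1L
      gid <- gb_qualifier(quals, c("locus_tag", "gene", "protein_id"))
      if (is.null(gid)) gid <- sprintf("%s_CDS%d", id, n_cds)
      pl <- tryCatch(parse_gb_location(loc), error = function(e) {
        warning("record ", id, ": skipping CDS with unparseable location '",
                loc, "'", call. = FALSE)
        NULL
      })
      if (is.null(pl)) next
      if (any(pl$intervals < 1) || any(pl$intervals > nchar(nt)) ||
          any(pl$intervals[, 2] < pl$intervals[, 1])) {
        warning("record ", id, ": skipping CDS outside sequence bounds (",
                loc, ")", call. = FALSE)
        next
      }
      cds_seq <- extract_cds_sequence(nt, pl$intervals, pl$strand)
      genes[[length(genes) + 1L]] <- gene(
        id = gid, genome_id = id, nt_sequence = cds_seq,
        start = min(pl$intervals[, 1]) - 1L, end = max(pl$intervals[, 2]),
        strand = pl$strand)
    }
  }
  meta <- list()
  if (!is.null(organism)) meta$organism <- organism
  genome(id, nt, genes = genes, name = name, metadata = meta)
}

gb_qualifier <- function(quals, keys) {
  for (k in keys) {
    hit <- grep(sprintf('^/%s="?', k), quals, value = TRUE)
    if (length(hit)) {
      return(gsub('"', "", sub(sprintf("^/%s=", k), "", hit[1])))
    }
  }
  NULL
}

#' Write a corpus as a GenBank flat file
#'
#' Emits the minimal subset of the format that [read_genbank()] reads back:
#' LOCUS/DEFINITION/ACCESSION/ORGANISM headers, CDS features with
#' `/locus_tag` qualifiers (minus-strand genes as `complement(a..b)`), and
#' the ORIGIN sequence. Used chiefly to persist synthetic corpora.
#'
#' @param x A corpus.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in x$genomes) {
    n <- nchar(g$nt_sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   VRL",
                       g$id, n), con)
    writeLines(sprintf("DEFINITION  %s", g$name), con)
    writeLines(sprintf("ACCESSION   %s", g$id), con)
    if (!is.null(g$metadata$organism)) {
      writeLines("SOURCE      .", con)
      writeLines(sprintf("  ORGANISM  %s", g$metadata$organism), con)
    }
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    for (gn in g$genes) {
      loc <- sprintf("%d..%d", gn$start + 1L, gn$end)
      if (gn$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', gn$id), con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(g$nt_sequence)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
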