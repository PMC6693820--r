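#' Pipeline configuration
#'
#' Gathers every stage parameter with its default, plus input/output
#' paths. The resolved configuration is written alongside every output
#' directory for provenance.
#'
#' @param input Path to a GenBank flat file or FASTA, or `NULL` to
#'   simulate a corpus from `sim` instead.
#' @param out_dir Output directory (created if missing).
#' @param sim A [simulation_config()] used when `input` is `NULL`.
#' @param aligner `"internal"` or `"tabular:<path>"` pointing at 12-column
#'   hits computed externally on the gene FASTA the pipeline writes.
#' @param k Word size for the k-mer metric.
#' @param kmer_weighting `"uniform"` or `"token"`, see [kmer_vi_matrix()].
#' @param min_bitscore,epsilon Gene-metric parameters (bits).
#' @param mds_dims,perplexity,theta,n_restarts Embedding parameters.
#' @param min_samples,xi Clustering parameters.
#' @param knn_k Neighbour count for downstream classification.
#' @param seed Integer seed for simulation and t-SNE.
#' @param merge_segments Merge GenBank records sharing an organism name.
#' @param kmer_only Skip gene extraction/alignment and embed the k-mer VI
#'   matrix alone — the mode for unannotated FASTA corpora.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out_dir = "virtaxa_out",
                            sim = simulation_config(),
                            aligner = "internal", k = 4L,
                            kmer_weighting = "uniform",
                            min_bitscore = 50, epsilon = 1e-6,
                            mds_dims = 50L, perplexity = 30, theta = 0.5,
                            n_restarts = 20L, min_samples = 5L, xi = 0.05,
                            knn_k = 30L, seed = 1L,
                            merge_segments = FALSE, kmer_only = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_key <- function(params, input_files) {
  sums <- tools::md5sum(input_files[file.exists(input_files)])
  digest::digest(list(params, unname(sums)))
}

## run `fun` unless its inputs+params are unchanged and outputs exist
run_stage <- function(name, cache, params, input_files, output_files, fun,
                      verbose = TRUE) {
  key <- stage_key(params, input_files)
  if (identical(cache$keys[[name]], key) && all(file.exists(output_files))) {
    if (verbose) message("[", name, "] up to date, skipped")
    return(cache)
  }
  if (verbose) message("[", name, "] running")
  ok <- tryCatch({
    fun()
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  cache$keys[[name]] <- key
  jsonlite::write_json(cache$keys, cache$path, auto_unbox = TRUE)
  cache
}

#' Run the full taxonomy pipeline
#'
#' Executes extract-genes, align, gene-distance, k-mer distance, combine,
#' MDS, t-SNE, OPTICS and dendrogram in order, writing each stage's output
#' to `out_dir` as plain text. Stages whose inputs and parameters are
#' unchanged (content-hash keyed) are skipped on re-runs; deleting an
#' intermediate file re-triggers that stage and its downstreams.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the key outputs (`corpus`, `gene_dist`,
#'   `kmer_vi`, `combined`, `embedding`, `clustering`, `dendrogram`,
#'   `paths`, `log`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  cache <- list(path = p(".stage_keys.json"), keys = list())
  if (file.exists(cache$path)) {
    cache$keys <- jsonlite::read_json(cache$path)
  }
  log <- list(version = as.character(packageVersion("virtaxa")))

  ## corpus: simulate or copy input
  corpus_path <- p("corpus.gb")
  if (is.null(config$input)) {
    cache <- run_stage("simulate", cache, config$sim, character(0),
                       c(corpus_path, p("families.tsv")), function() {
      sim <- simulate_corpus(config$sim)
      write_genbank(sim$corpus, corpus_path)
      write_family_labels(sim$families, p("families.tsv"))
    }, verbose)
    crp <- read_genbank(corpus_path)
  } else {
    corpus_path <- config$input
    crp <- if (grepl("\\.(gb|gbk|genbank)$", config$input)) {
      read_genbank(config$input, merge_by_organism = config$merge_segments)
    } else {
      read_fasta(config$input)
    }
  }

  ## extract genes
  if (!config$kmer_only) {
  cache <- run_stage("extract_genes", cache, list(), corpus_path,
                     p("genes.fasta"), function() {
    write_gene_fasta(crp, p("genes.fasta"))
  }, verbose)

  ## align
  params <- aligner_params(min_bitscore = config$min_bitscore)
  hits_path <- p("gene_hits.tsv"); self_path <- p("gene_self.tsv")
  if (identical(config$aligner, "internal")) {
    cache <- run_stage("align", cache, params, p("genes.fasta"),
                       c(hits_path, self_path), function() {
      sc <- align_corpus(crp, params)
      write.table(sc$hits, hits_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(data.frame(gene_id = names(sc$entropy),
                             bitscore = unname(sc$entropy)),
                  self_path, sep = "\t", quote = FALSE, row.names = FALSE)
    }, verbose)
    hits_df <- read.table(hits_path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric"))
    self_df <- read.table(self_path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
    scores <- structure(list(
      entropy = setNames(self_df$bitscore, self_df$gene_id),
      hits = hits_df), class = "gene_score_table")
  } else if (startsWith(config$aligner, "tabular:")) {
    tab <- sub("^tabular:", "", config$aligner)
    scores <- tabular_score_table(parse_tabular_hits(tab, crp), crp)
  } else {
    stop("unknown aligner backend: ", config$aligner)
  }

  ## gene distance
  align_inputs <- if (identical(config$aligner, "internal")) {
    c(hits_path, self_path)
  } else {
    sub("^tabular:", "", config$aligner)
  }
  cache <- run_stage("gene_dist", cache,
                     list(epsilon = config$epsilon), align_inputs,
                     p("gene_dist.tsv"), function() {
    D <- gene_distance_matrix(crp, scores, epsilon = config$epsilon)
    log$n_clamped_vi <<- attr(D, "n_clamped")
    write_distance_matrix(D, p("gene_dist.tsv"))
  }, verbose)
  gene_D <- read_distance_matrix(p("gene_dist.tsv"))
  } # end !kmer_only

  ## k-mer distance
  cache <- run_stage("kmer_dist", cache,
                     list(k = config$k, w = config$kmer_weighting),
                     corpus_path, p("kmer_vi.tsv"), function() {
    K <- kmer_vi_matrix(crp, k = config$k, weighting = config$kmer_weighting)
    write_distance_matrix(K, p("kmer_vi.tsv"))
  }, verbose)
  kmer_D <- read_distance_matrix(p("kmer_vi.tsv"))

  ## combine
  if (config$kmer_only) {
    cache <- run_stage("combine", cache, list(kmer_only = TRUE),
                       p("kmer_vi.tsv"), p("combined.tsv"), function() {
      write_distance_matrix(kmer_D, p("combined.tsv"))
    }, verbose)
  } else {
    cache <- run_stage("combine", cache, list(),
                       c(p("gene_dist.tsv"), p("kmer_vi.tsv")),
                       p("combined.tsv"), function() {
      C <- combine_distances(gene_D, kmer_D)
      log$rescale_factor <<- attr(C, "rescale_factor")
      write_distance_matrix(C, p("combined.tsv"))
    }, verbose)
  }
  comb_D <- read_distance_matrix(p("combined.tsv"))

  ## MDS
  cache <- run_stage("mds", cache, list(dims = config$mds_dims),
                     p("combined.tsv"), p("mds.tsv"), function() {
    X <- classical_mds(comb_D, dims = config$mds_dims)
    log$n_clipped_eigenvalues <<- attr(X, "n_clipped")
    write.table(data.frame(id = rownames(X), X, check.names = FALSE),
                p("mds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }, verbose)
  mds_df <- read.table(p("mds.tsv"), sep = "\t", header = TRUE)
  mds_X <- as.matrix(mds_df[, -1])
  rownames(mds_X) <- mds_df$id

  ## t-SNE
  tsne_pars <- list(perplexity = config$perplexity, theta = config$theta,
                    n_restarts = config$n_restarts, seed = config$seed)
  cache <- run_stage("tsne", cache, tsne_pars, p("mds.tsv"),
                     c(p("tsne.tsv"), p("tsne_kl.json")), function() {
    emb <- tsne_embed(mds_X, perplexity = config$perplexity,
                      theta = config$theta,
                      n_restarts = config$n_restarts, seed = config$seed)
    write.table(data.frame(id = emb$ids, emb$tsne_coords),
                p("tsne.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(kl_divergence = emb$kl_divergence,
                              kl_all = emb$kl_all,
                              perplexity = emb$perplexity),
                         p("tsne_kl.json"), auto_unbox = TRUE, digits = NA)
  }, verbose)
  ts_df <- read.table(p("tsne.tsv"), sep = "\t", header = TRUE)
  ts_X <- as.matrix(ts_df[, -1])
  rownames(ts_X) <- ts_df$id

  ## OPTICS
  cl_pars <- list(min_samples = config$min_samples, xi = config$xi)
  cache <- run_stage("cluster", cache, cl_pars, p("tsne.tsv"),
                     p("clusters.tsv"), function() {
    clst <- optics_clusters(ts_X, min_samples = config$min_samples,
                            xi = config$xi)
    write.table(data.frame(id = clst$ids, cluster = clst$labels,
                           reachability = clst$reachability),
                p("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }, verbose)
  cl_df <- read.table(p("clusters.tsv"), sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "numeric"))
  clustering <- structure(list(ids = cl_df$id, labels = cl_df$cluster,
                               reachability = cl_df$reachability,
                               params = cl_pars),
                          class = "virtaxa_clustering")

  ## dendrogram
  dend <- NULL
  if (length(unique(cl_df$cluster[cl_df$cluster >= 0])) >= 2) {
    cache <- run_stage("dendrogram", cache, list(), p("clusters.tsv"),
                       p("dendrogram.nwk"), function() {
      d <- cluster_dendrogram(ts_X, cl_df$cluster)
      writeLines(d$newick, p("dendrogram.nwk"))
    }, verbose)
    dend <- cluster_dendrogram(ts_X, cl_df$cluster)
  } else if (verbose) {
    message("[dendrogram] fewer than 2 clusters, skipped")
  }

  ## provenance
  cfg <- config
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  jsonlite::write_json(log, p("log.json"), auto_unbox = TRUE, digits = NA)

  if (config$kmer_only) gene_D <- NULL
  invisible(list(corpus = crp, gene_dist = gene_D, kmer_vi = kmer_D,
                 combined = comb_D,
                 embedding = list(mds_coords = mds_X, tsne_coords = ts_X),
                 clustering = clustering, dendrogram = dend,
                 log = log,
                 paths = list(out_dir = config$out_dir)))
}
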