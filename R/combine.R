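#' Rescale factor matching the k-mer VI to the gene-distance scale
#'
#' Finite gene-alignment distances run to tens of thousands of bits while
#' the binary k-mer VI is at most 2 bits; combined as parallel resistors
#' the small k-mer values would short-circuit everything. The k-mer matrix
#' is therefore rescaled so that its maximum equals the maximum finite
#' gene-alignment distance.
#'
#' @param gene_matrix Gene distance matrix (sentinels `Inf` allowed).
#' @param kmer_matrix K-mer VI matrix (finite).
#' @return Positive scale factor
#'   `s = max finite off-diagonal gene distance / max off-diagonal k-mer VI`.
#' @export
rescale_factor <- function(gene_matrix, kmer_matrix) {
  off <- row(gene_matrix) != col(gene_matrix)
  g <- gene_matrix[off]
  g <- g[is.finite(g)]
  if (length(g) == 0) {
    stop("no finite gene-alignment distance; use the k-mer matrix alone")
  }
  kmax <- max(kmer_matrix[off])
  if (kmax <= 0) stop("k-mer VI matrix has no positive off-diagonal entry")
  max(g) / kmax
}

#' Combine gene and k-mer distances as parallel resistors
#'
#' D = 1 / (1/D_gene + 1/(s * D_kmer)); where the gene distance is the
#' no-match sentinel (an open circuit) the combined distance is the
#' rescaled k-mer VI alone. The diagonal is 0 and every off-diagonal entry
#' is finite.
#'
#' @param gene_matrix Gene distance matrix with `Inf` sentinels.
#' @param kmer_matrix K-mer VI matrix.
#' @param s Scale factor, computed with [rescale_factor()] when omitted.
#' @return Finite symmetric matrix (bits), zero diagonal; attribute
#'   `rescale_factor` records `s`.
#' @export
combine_distances <- function(gene_matrix, kmer_matrix, s = NULL) {
  stopifnot(identical(dimnames(gene_matrix), dimnames(kmer_matrix)))
  if (is.null(s)) s <- rescale_factor(gene_matrix, kmer_matrix)
  stopifnot(s > 0)
  sk <- s * kmer_matrix
  D <- 1 / (1 / gene_matrix + 1 / sk)  # Inf gene entries drop out: 1/Inf = 0
  D[is.infinite(gene_matrix)] <- sk[is.infinite(gene_matrix)]
  diag(D) <- 0
  attr(D, "rescale_factor") <- s
  D
}
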