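---
title: "Genome distances from gene-level variation of information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome distances from gene-level variation of information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`virtaxa` treats a viral genome as a collection of genes and asks how much
information two genomes share. For a pair of genes, the translated local
alignment bit score is read as their mutual information $I$ (the bit score
is the log2 size of a database in which an equally good match arises by
chance, and is proportional to mutual information). Each gene's entropy is
its self-alignment score, $H(A_i) = I(A_i, A_i)$, and the dissimilarity of
a gene pair is the variation of information

$$D(A_i, B_j) = H(A_i) + H(B_j) - 2\,I(A_i, B_j),$$

a true metric on random variables. Gene-pair distances are combined into a
genome distance the way resistances combine in parallel:

$$D_{eq}(A, B) = \left( \sum_{\text{matched pairs } (i,j)}
\frac{1}{D(A_i, B_j)} \right)^{-1}.$$

The electrical analogy carries the model's three axioms: a single shared
gene makes the genome distance equal that gene's distance; every
additional match can only pull genomes closer; unmatched pairs are open
circuits and contribute nothing. Genome pairs with *no* matched gene have
infinite equivalent resistance — the no-match sentinel.

Where alignment fails entirely, a coarser channel remains: for each genome,
each of the 256 possible 4-mers is scored as over- or under-represented
relative to the pooled frequency across the whole corpus. Over/under
representation of a uniformly drawn 4-mer type is then a binary random
variable per genome, and the same variation-of-information construction
applies, with the mutual information summed over the four over/under cell
combinations. This k-mer VI is bounded by 2 bits (two binary variables)
and finite for every genome pair. Because finite gene distances reach tens
of thousands of bits while the k-mer VI lives in $[0, 2]$, the k-mer
matrix is rescaled so its maximum equals the maximum finite gene distance,
then added as one more parallel resistor:

$$D = \left( \frac{1}{D_{gene}} + \frac{1}{s \cdot D_{kmer}} \right)^{-1},
\qquad s = \frac{\max D_{gene}^{finite}}{\max D_{kmer}}.$$

The combined matrix is noisy and violates the triangle inequality, so it
is smoothed rather than used raw: classical (Torgerson) MDS to 50
dimensions, Barnes–Hut t-SNE to 3 dimensions (perplexity 30, theta 0.5, 20
restarts keeping the lowest final KL divergence), OPTICS density
clustering on the 3-D embedding, and an average-linkage dendrogram over
the clusters. New genomes are placed into an existing clustering without
any new alignments: a size-weighted k-nearest-neighbour vote on the k-mer
VI against the frozen reference.

## Parameters that matter

* `min_bitscore` (bits, default **50**). Hits below this floor are treated
  as no match. The built-in aligner is exact Smith–Waterman over all 36
  frame pairs with no e-value or database-size correction, so its chance
  score level for genes of around a hundred codons is roughly
  $\ln(mn)/\lambda \approx 17$ bits plus extreme-value fluctuation —
  measured chance maxima reach the mid-20s, while genuinely homologous
  genes score upwards of ~90 bits. A floor of 50 sits far above chance and
  far below signal; it is configurable for corpora with very short genes.
* `epsilon` (bits, default `1e-6`). Alignment heuristics can push $I$
  beyond the entropies and make a VI negative; negative values are raised
  to this floor so they cannot dominate (or zero out) the parallel sum.
  It must simply be far below any genuine VI.
* Karlin–Altschul constants `lambda = 0.267`, `K = 0.041` (standard gapped
  BLOSUM62 values, gap open 11 / extend 1). Only the overall scale of the
  gene distance depends on them, and the k-mer rescaling absorbs scale.
* `k = 4` for the k-mer metric: 256 types, counted in every sliding
  window, windows containing N excluded. Ties against the baseline count
  as under-represented (ties are measure-zero on real data but common in
  small fixtures, so the rule is fixed). Counting is single-strand; no
  reverse-complement canonicalisation.
* Probabilities over 4-mer types are uniform (each type weighs 1/256);
  a token-weighted variant (types weighted by pooled corpus frequency) is
  exposed as `weighting = "token"` for comparison but is not the default.
* t-SNE: perplexity 30, auto-reduced to `floor((n-1)/3)` with a warning on
  small corpora; `theta = 0.5`; 20 restarts, restart $r$ seeded
  `seed + r - 1`, minimum-KL result kept; 3 output dimensions.
* OPTICS: `min_samples = 5`, xi-style extraction with `xi = 0.05`
  (validated against a reference OPTICS implementation), with a
  reachability-threshold (DBSCAN-equivalent) extraction as an alternative.
* Classifier: weight $w(s) = 1/s$ on cluster size — the simplest rule that
  lets clusters smaller than the neighbourhood ever win — and `k = 30`
  neighbours by default, matching a reference set of thousands. **At desk
  scale the neighbour count must be chosen below the typical cluster
  size**, and odd, or the size-weighted vote between two pure
  neighbourhoods can tie exactly (each cluster's total weight is
  $s \cdot 1/s = 1$); the bundled studies use `k = 9` against clusters of
  10.

## What the synthetic generator emulates

Each family descends from an ancestor genome: 4–6 protein-coding genes of
60–120 codons (ATG start, no internal stop) on mixed strands, separated by
intergenic regions of 150–400 bases. Descendants apply independent
per-site substitutions (rate 0.05 by default), whole-gene loss (0.1 per
gene) and gain of novel genes (0.1 per genome). Intergenic regions belong
to the ancestor and are inherited and mutated exactly like genes — real
viral UTRs and packaging signals are homologous within a family, and this
is what gives the 4-mer spectrum its family signature (shared sequence
content contributes far more to it than the per-family GC bias, which
defaults to 0.35–0.65 across families). Genomes come out at roughly 2–3 kb
— small-virus scale. The non-coding fraction (~40%) is higher than in most
real viral genomes; it was chosen so the 4-mer statistics have adequate
token counts (~10 per type) at corpus sizes whose all-pairs translated
alignment stays affordable, and the bundled analyses use corpora of 30–50
genomes for the same reason.

What the generator does *not* model: indels (substitution plus gene
gain/loss only), recombination, codon usage structure beyond GC bias,
horizontal transfer between families (gained genes are novel), and
segmented genomes (each genome is one record; the GenBank reader's
organism-merge flag handles multi-record input instead). Consequently,
passing tests show that the statistics and the pipeline do what they claim
under clean family structure with calibrated divergence; they do not show
that real viral taxa are recovered at RefSeq scale or under recombination.

## Numerical choices and degenerate inputs

* The VI floor (`epsilon`) and the no-match sentinel (`Inf`, serialized as
  `inf` in TSV) are the only two special values; the diagonal is defined
  as 0 rather than computed.
* One score per unordered gene pair: the maximum over both orderings and
  all local alignments, not a sum — summing overlapping alignments would
  double-count shared information. Matches between genes of the same
  genome are discarded.
* MDS clips negative eigenvalues to zero and reports how many (they are
  expected: the input is non-metric); coordinates beyond the positive
  spectrum are zero-filled so the output always has `dims` columns.
* Equality ties: a 4-mer exactly at its baseline frequency is
  under-represented; a tied k-NN vote goes to the lower cluster id and is
  logged.
* Genomes shorter than `k` (no countable window) are an error for the
  k-mer metric; genes shorter than one codon are no-match for the aligner.
* t-SNE determinism: each restart re-seeds R's RNG; identical seeds give
  byte-identical embeddings, labels and dendrograms.

## Design choices where the design was open

* **Aligner engine.** The six-frame translated aligner is exact local DP
  (Smith–Waterman, affine gaps) in compiled code, checked in the test
  suite against a naive full-matrix DP oracle and against
  `Biostrings::pairwiseAlignment`. It deliberately omits the search
  heuristics of production tools (seeding, two-hit extension, e-value
  corrections); for large corpora the pipeline ingests 12-column tabular
  hits from an external translated search instead.
* **Bit score as mutual information.** The proportionality constant is
  fixed at 1; any other value is absorbed by the k-mer rescale factor.
* **Dendrogram construction.** Average linkage (UPGMA) on mean pairwise
  Euclidean distances between cluster members in the 3-D embedding, noise
  excluded. Branch lengths are a confidence score for a cluster's
  distinctness, not evolutionary time.
* **Sub-cluster analysis** is plain recursion: OPTICS re-run on one
  cluster's rows of the embedding, no special casing.
* **Segment merging** is opt-in (`merge_by_organism`), since public
  records key segments inconsistently.
* **Frozen baseline.** New genomes never update the reference 4-mer
  baseline or flags; placement is meant to be incremental.

## Known limitations

* The gene distance is only as good as its score floor: near the floor,
  borderline homologies flip between sentinel and finite, which moves the
  rescale factor. No outlier trimming is applied to the max before
  rescaling, by design.
* t-SNE preserves neighbourhoods, not global geometry; inter-cluster
  distances in the dendrogram inherit that distortion.
* The binarized k-mer representation discards magnitude information; on
  very short genomes (under ~1 kb) its 256-cell statistics are noisy.
* OPTICS xi extraction can split one family into sub-clusters when its
  density profile is uneven; the adjusted Rand index is the right measure
  of recovery, not the raw cluster count.
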