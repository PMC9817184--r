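Package: hybridcensus
Title: Hybrid Parentage Inference from Best-Hit Read Censuses and Gene-Tree Sister Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers the parentage of a putative interspecies hybrid from
    whole-genome short reads and a forest of gene trees. Reads are quality
    filtered and aligned against a balanced, species-tagged database of
    fixed-length genome fragments using a k-mer seeded, banded Smith-Waterman
    local aligner with Karlin-Altschul E-values; each read keeps its single
    best hit, cross-species ties are discarded, and the per-species census of
    unique best hits identifies the two parents. A parallel census against a
    mitochondrial database identifies the dam. A sister-taxon census over
    outgroup-rooted gene trees corroborates the parent pair, and exact
    binomial tests on parent-assigned read counts classify the hybrid as F1
    (50 percent expected ancestry per parent) or first-generation backcross
    (75 percent). Includes a seeded simulator of parent genomes under
    Jukes-Cantor divergence, F1/BC1 hybrid genomes with recombination and
    maternal mitochondrial inheritance, error-bearing short reads, and
    gene-tree forests with controllable sister-species mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
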