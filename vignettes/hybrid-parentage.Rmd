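---
title: "Inferring hybrid parentage from best-hit read censuses and gene-tree sister censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hybrid parentage from best-hit read censuses and gene-tree sister censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcensus)
```

## The inference problem

A putative interspecies hybrid has been whole-genome sequenced at short-read
scale, and genome assemblies exist for a panel of candidate parent species.
The question is threefold: which two species are the parents, which of them
is the dam (mother), and is the specimen a first-generation (F1) hybrid or a
first-generation backcross (BC1, an F1 crossed back to one parent)?

`hybridcensus` answers all three with censuses:

1. **Nuclear best-hit census.** Every read is aligned against a *balanced*
   database of genome fragments, one pool per candidate species; the read's
   single best hit (lowest E-value) votes for one species, and reads whose
   best hit is tied across two or more species are discarded. An F1 sends
   roughly equal vote shares to its two parents; a BC1 sends roughly 75% of
   the parental votes to the backcrossed parent.
2. **Mitochondrial census.** The same procedure against a database of
   mitochondrial genomes only. Mitochondria are maternally inherited, so the
   mito census should be nearly unanimous for the dam.
3. **Gene-tree sister census.** Across a forest of single-copy ortholog
   trees containing the hybrid, the species most often found as the hybrid's
   sister taxon corroborate the parent pair.

## The read-census model

### Balanced fragment databases

Assemblies differ enormously in size and contiguity, which would bias raw
hit counts. Each assembly is therefore partitioned into non-overlapping
fragments of exactly `fragment_length` bases (default 100) starting at
position 0 of each contig, terminal remainders discarded, and an equal
number of fragments per species is retained by uniform subsampling without
replacement (`sample_fragments()`). At the scale of the design this
procedure stands for — a million 100-bp fragments per species — the retained
pool is about 10% of a 1-Gb assembly. Whole mitogenomes are tiled but not
subsampled; at ~16 kb they are already comparable across species.

Two conventions here were genuinely open and are fixed as package
definitions: tiling is disjoint from position 0 (a "partition"), and the
sub-fragment remainder of each contig is discarded rather than padded.

### Seed-and-extend alignment and E-values

Reads are aligned by the classic seed-and-extend scheme: exact k-mers
(default k = 11, the classic blastn word size) shared between the read and a
fragment nominate candidate fragments via a counting-sort k-mer index; each
candidate is then scored by banded affine-gap Smith–Waterman restricted to
the seeded diagonals ± `band` (default 15). The database stores the forward
strand only; each read is searched as-is and as its reverse complement,
which halves the index while keeping the search strand-complete. Scoring is
match +1, mismatch −2, and gap cost 5 + 2L for a gap of length L.

Raw scores S are converted to bit scores S′ = (λS − ln K)/ln 2 and E-values
E = m·n·2^(−S′), with m the read length and n the total database length.
λ = 1.28 and K = 0.46, standard values for the +1/−2 scheme, are configurable;
since the census uses E-values only to rank hits within a read and to set a
floor (`e_max`, default 10⁻³), the inference is insensitive to their exact
calibration. `e_max` is deliberately exposed as configuration: it is an
operating point of this implementation, not an empirical constant.

The banded path is not trusted by fiat: the test suite checks it against a
full-matrix Smith–Waterman reference on exhaustive small databases, and that
reference in turn against an independent implementation
(`Biostrings::pairwiseAlignment`).

### Best hits, ties, and the census

Per read, the minimal-E alignment wins. If two or more *species* achieve the
minimal E — bit scores equal within a 10⁻⁶ relative tolerance, which
reproduces exact-tie discarding at floating-point level — the read is
discarded as uninformative; several tied fragments of the *same* species are
not a tie. Reads with no alignment under `e_max` are no-hits. The census
reports per-species counts and proportions over assigned (unique best hit)
reads, with tie and no-hit tallies kept alongside so that
`n_assigned + n_tie_discarded + n_no_hit` always equals the query count.
"Unique best hits" is defined per query read (one vote per read), not per
high-scoring pair; that is this package's reading of an ambiguous term of
art, recorded here.

## The gene-tree sister census

Each tree is rooted on a designated outgroup leaf (trees lacking the
outgroup are tallied as unrootable and excluded — sisterhood is undefined
without a root). The sister group of the focal tip is the union of leaves of
the other children of its parent node; under a multifurcating parent this is
automatically non-singleton. Only trees whose sister group is exactly one
leaf count toward the census — the singleton-sister filter — because a
multi-leaf sister does not vote for a single species. Proportions are
reported over singleton-sister trees. Branch lengths are ignored throughout;
the census is purely topological.

## F1 versus BC1

Let c₁ and c₂ be the read counts assigned to the two parents (c₁ the dam's
parent when the dam is known). The generation class is decided by exact
two-sided binomial tests of c₁/(c₁+c₂) against three models: p = 0.5 (F1),
p = 0.75 (BC1 toward parent 1), p = 0.25 (BC1 toward parent 2), at
α = 0.001. The call is the unique retained model; if none or several are
retained the call is ambiguous. Swapping (c₁, c₂) maps the two BC1 calls
onto each other and leaves F1/ambiguous unchanged.

### Effective sample size

Read counts dramatically overstate the number of independent draws from the
genome-wide ancestry proportion: reads sampled from the same parental
segment are perfectly correlated in origin. The relevant unit is the
independently segregating segment. Under the default simulated karyotype —
C = 10 chromosomes, one crossover each — the BC1 recombinant haplotype's
backcross-parent fraction is a mean of C independent uniforms, so the
genome-wide ancestry proportion has standard deviation
1/(2·√(12·C)) ≈ 0.046 around 0.75. A binomial proportion at p = 0.75 has
that same standard deviation at n ≈ 90. The pipeline therefore tests at an
effective count of 100 (`downsample = 100`), preserving the observed
proportion: at read-count n the exact tests would reject the true 0.75 model
for most genuine BC1s simply because each genome's realized ancestry is not
exactly 0.75. `classify_generation()` itself defaults to the raw counts so
the pure decision rule remains available, and every report carries the
caveat.

The same reasoning means the per-replicate parental share is
*extra-binomial*: it estimates that genome's realized ancestry, not 0.75.
The 75% expectation is recovered as a mean across replicates, and the test
suite checks exactly that, plus per-replicate agreement between the census
share and the genome's own origin track within binomial error.

## What the simulator emulates — and what it does not

The generator exists so that every stage can be exercised against known
truth with seeded determinism (identical configs give byte-identical FASTA,
FASTQ and Newick outputs).

* **Species** sit on a star phylogeny: each evolves from a shared uniform
  random ancestor by Jukes–Cantor substitution along its own branch d, so a
  site differs from the ancestor with probability p = ¾(1 − e^(−4d/3)) and
  pairwise divergences follow d₁ + d₂. JC69 is the simplest model that
  provides the only lever the censuses respond to — divergence. Default
  branches of 0.05 give ~9.4% observed pairwise divergence, a deliberately
  generous stand-in for deeply diverged candidate parents.
* **Karyotype**: 10 chromosomes of 10 kb by default. Desk-scale, but
  multi-chromosome on purpose: independent segregation is what concentrates
  BC1 ancestry near 0.75 (one single chromosome would leave it uniform on
  [0.5, 1]).
* **Crosses**: an F1 takes one full haplotype per parent and the dam's
  mitogenome verbatim; a BC1 takes one full haplotype from the backcrossed
  parent plus a recombinant F1 gamete with `n_crossovers` (default 1)
  uniformly placed crossovers per chromosome. A per-base origin track
  records ground truth. How many crossovers a real BC1 carries per
  chromosome is left as a parameter rather than asserted.
* **Reads** are single-end with uniform starts, random strand, and
  independent per-base substitution errors; quality strings are constant at
  the Phred encoding of the error rate. Pairing, indels, structural
  variation, and instrument-specific quality profiles are deliberately out
  of scope — none of them feed the best-hit census. One consequence is
  handled explicitly: a 0.5% error rate encodes as Q23, so the composed
  pipeline caps its quality-trimming threshold at the simulated quality
  (the usual Phred-30 trim would otherwise erase every base); the 30/30/30
  QC defaults stand for externally supplied reads.
* **Gene trees** realize a specified sister-category mixture directly —
  Bernoulli per tree, or by exact quota so fixtures can reproduce a target
  census table to the tree. Background topology is randomized, branch
  lengths are all 1. The generator does *not* simulate coalescent
  processes: incomplete lineage sorting, the biological reason the sister
  census of a real hybrid is split between the parents rather than
  unanimous, enters only through the mixture weights you choose.

Because of these simplifications, passing tests demonstrate that the
*census machinery* — alignment, tie discarding, balancing, rooting,
filtering, classification — is correct and well calibrated under known
truth. They do not demonstrate robustness to assembly contamination,
low-complexity sequence, indel-rich divergence, or reference bias in real
data.

## Numerical and degenerate-input choices

* Alignment reporting floor: the raw-score threshold implied by `e_max` for
  the shortest read in a batch; exact E filtering is then applied per read.
* Ties: relative bit-score tolerance 10⁻⁶.
* Repetitive seeds occurring in more than `max_kmer_hits` postings are
  skipped (no low-complexity masking is attempted beyond this).
* `sample_fragments()` asked for more fragments than exist keeps everything
  with a warning, so small simulated genomes work.
* Reads shorter than k cannot seed and are no-hits; empty alignment sets,
  empty mito censuses, missing outgroups, and sub-2-species censuses all
  produce defined outcomes or named errors rather than crashes.
* Parent identification breaks exact second-place ties lexicographically,
  with a warning.
* Dam assignment requires the top mito species to reach 0.99 of
  mito-assigned reads *and* to be one of the two nuclear parents; 0.99
  mirrors near-unanimity while leaving room for the chance alignments that
  nuclear reads contribute at desk scale.

## Problem sizes

The shipped analyses and the acceptance script run at desk scale, chosen as
the package's own operating point: 4 candidate species, 100 kb nuclear
genomes, 16 kb mitogenomes, 20,000 reads per specimen, 20 seeded replicates
per cross, and an 8063-tree quota fixture with 5910 singleton-sister trees
(45% / 34% / 0.2% across the three named species of its reference table).
At this scale the full workflow completes in minutes on one CPU.

## Known limitations

* E-value calibration is approximate (ungapped λ, K applied to gapped
  scores); rankings, not absolute E-values, carry the inference.
* The classifier covers F1 and BC1 only; later generations (F2 intercross,
  BC2+) and admixture-proportion estimation are out of scope.
* The extra-binomial variance of ancestry proportions is handled by an
  effective-count correction, not modeled explicitly.
* The sister census assumes the outgroup is a valid root; a misspecified
  outgroup silently redefines sisterhood.
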