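# hybridcensus

Genomic validation of hybrid parentage from whole-genome short reads and
gene trees. Given a putative interspecies hybrid, a panel of candidate
parent assemblies, and a forest of single-copy ortholog trees, the package
answers three questions: **which two species are the parents**, **which
parent is the dam**, and **is the specimen an F1 or a first-generation
backcross (BC1)?** It is written for the situation that motivates it —
historical or museum hybrid specimens whose phenotype-based identifications
need genetic re-examination — and every stage also runs against a built-in,
fully seeded simulator so the machinery can be validated end to end on known
truth.

## Method

1. **Balanced best-hit read census.** Each candidate assembly is partitioned
   into 100-bp fragments and an equal number of fragments per species is
   subsampled, removing assembly-size bias. Quality-filtered reads (3'
   Phred trim, minimum length, masked-base cap) are aligned on both strands
   by a k-mer-seeded (k = 11), banded affine Smith–Waterman aligner; scores
   become bit scores S' = (λS − ln K)/ln 2 and E-values E = m·n·2^(−S'). Per
   read, the lowest-E hit votes for one species; reads tied across species
   at the minimal E are discarded. An F1 gives its two parents roughly equal
   vote shares; a BC1 gives the backcrossed parent ~75% of the parental
   votes.
2. **Mitochondrial census.** The same procedure against a
   mitogenome-only database identifies the dam (maternal inheritance: the
   mito census should be near-unanimous).
3. **Gene-tree sister census.** Each ortholog tree is rooted on an outgroup;
   trees whose focal-tip sister is a single leaf (singleton-sister filter)
   vote for that species, corroborating the parent pair.
4. **Generation test.** With c₁, c₂ the parent-assigned counts, exact
   binomial tests of c₁/(c₁+c₂) against p = 0.5 (F1) and p = 0.75 / 0.25
   (BC1 either way) at α = 0.001 yield F1, BC1-toward-a-parent, or
   ambiguous, at a linkage-matched effective sample size (see the methods
   vignette in `vignettes/hybrid-parentage.Rmd`).

The simulator provides parent genomes under Jukes–Cantor divergence on a
star phylogeny, F1/BC1 hybrids with recombination and a per-base true-origin
track, maternally inherited mitogenomes, error-bearing reads (FASTQ), and
gene-tree forests with controllable sister mixtures (Newick) — all
byte-reproducible under a seed.

## Worked example

Simulate an F1 of species A × B (A the dam) with two decoy relatives, census
its reads, and call parentage:

```r
library(hybridcensus)

cfg <- sim_config(seed = 7, hybrid_cross = "F1", mito_read_fraction = 0.1)
call <- run_pipeline(cfg)
print(call)
#> parentage_call
#>   parents   : A, B
#>   dam       : A (mito proportion 0.9995)
#>   generation: F1  (p_hat = 0.5032; p[0.5] = 1, p[0.75] = 8.4e-08, p[0.25] = 8.4e-08)
#>   note: read counts overstate independent draws; see downsample option
```

The two parents receive near-equal shares of the ~18,000 assigned reads
(p̂ = 0.503, so the F1 model p = 0.5 is retained and both backcross models
are rejected), the mito census is >99% unanimous for A, and the decoys
collect almost nothing. A BC1 simulated toward A instead yields

```r
cfg <- sim_config(seed = 7, hybrid_cross = "BC1", backcross_parent = "A",
                  mito_read_fraction = 0.1)
run_pipeline(cfg)$generation
#> [1] "BC1_toward(A)"
```

with ~71% of parent-assigned reads on A in that replicate (each genome's
realized ancestry scatters around 75%; the mean across replicates recovers
it).

The same pipeline is broken into narrative steps under `analysis/`
(01 simulate → 02 hit census → 03 tree census → 04 parentage), each writing
its tables under `results/`; run them in order from the repository root.

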