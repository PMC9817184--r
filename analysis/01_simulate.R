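#!/usr/bin/env Rscript
# Step 1 -- simulate the study inputs.
#
# Two specimens are generated under the default study conditions (four
# candidate species A-D on a star phylogeny, branch divergence 0.05, i.e.
# ~9.4% observed pairwise divergence; 10 x 10 kb chromosomes; 16 kb
# mitogenome; 20,000 reads of 100 bp at 0.5% error, 10% mitochondrial):
#   * an F1 of A x B with A as dam,
#   * a first-generation backcross (BC1) of that F1 toward A.
# Genomes, reads and a 300-tree gene forest (sister mixture centred on the
# true parents) are written under results/data/ as FASTA / FASTQ / Newick.

suppressPackageStartupMessages(library(hybridcensus))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

forest_spec <- gene_tree_forest_spec(
  n_trees = 300, taxa = c("hybrid", "A", "B", "C", "D", "outgroup"),
  focal = "hybrid", outgroup = "outgroup",
  sister_mixture = c(A = 0.45, B = 0.34, C = 0.02, D = 0.02),
  non_singleton_fraction = 0.17, seed = 900L)

for (cross in c("F1", "BC1")) {
  cfg <- sim_config(seed = 800L, hybrid_cross = cross,
                    backcross_parent = if (cross == "BC1") "A",
                    mito_read_fraction = 0.1)
  genomes <- simulate_parent_genomes(cfg)
  hybrid <- make_hybrid(genomes, cfg)
  reads <- simulate_reads(hybrid, cfg)
  dir <- file.path(out, cross)
  dir.create(dir, showWarnings = FALSE)
  write_genomes_fasta(genomes, file.path(dir, "genomes"))
  write_reads_fastq(reads, file.path(dir, "reads.fastq"))
  fr <- ancestry_fractions(hybrid)
  cat(sprintf("%s specimen: ancestry A = %.3f, B = %.3f; dam = %s; %d reads (%d mito)\n",
              cross, fr["A"], fr["B"], hybrid$dam, nrow(reads),
              sum(reads$origin_kind == "mito")))
}

write_newick_forest(simulate_gene_trees(forest_spec),
                    file.path(out, "forest.nwk"))
cat("gene-tree forest: 300 trees written to", file.path(out, "forest.nwk"), "\n")
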