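#!/usr/bin/env Rscript
# Step 3 -- gene-tree sister census.
#
# Loads the simulated 300-tree forest, roots every tree on the outgroup,
# extracts the focal tip's sister group, applies the singleton-sister filter,
# and censuses sister species. Also rebuilds the package's 8063-tree quota
# fixture and verifies its census reproduces the quota table exactly.

suppressPackageStartupMessages(library(hybridcensus))

tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

forest <- read_newick_forest("results/data/forest.nwk")
cen <- sister_census(forest, "hybrid", "outgroup")
print(cen)
write_census_tsv(cen, file.path(tab_dir, "tree_census.tsv"))

fx <- build_fixture_forest(seed = 17L)
fcen <- sister_census(fx$forest, fx$focal, fx$outgroup)
stopifnot(fcen$n_singleton == 5910L,
          fcen$counts["Gallus_gallus"] == fx$quota["Gallus_gallus"],
          fcen$counts["Numida_meleagris"] == fx$quota["Numida_meleagris"])
cat(sprintf(paste0(
  "fixture forest: %d trees, %d singleton-sister; ",
  "G. gallus %.1f%%, N. meleagris %.1f%%, P. pileata %.1f%% of singletons\n"),
  fcen$n_trees_total, fcen$n_singleton,
  100 * fcen$proportions["Gallus_gallus"],
  100 * fcen$proportions["Numida_meleagris"],
  100 * fcen$proportions["Penelope_pileata"]))
write_census_tsv(fcen, file.path(tab_dir, "fixture_tree_census.tsv"))
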