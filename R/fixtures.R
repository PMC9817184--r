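#' Quota table of the reference sister-census fixture
#'
#' Category counts for a deterministic 8063-tree forest: 5910 trees carry a
#' singleton sister (45% Gallus gallus, 34% Numida meleagris, 0.2% Penelope
#' pileata of the singletons, remainder spread over the other Galliformes in
#' the panel) and 2153 carry a multi-leaf sister clade. This is the package's
#' reference census table for the Gallus x Numida identification problem,
#' realized exactly by quota sampling.
#'
#' @return named integer vector of per-category tree counts (species names
#'   plus `"multi"`); sums to 8063.
#' @export
fixture_forest_quota <- function() {
  n_trees <- 8063L
  n_singleton <- 5910L
  gallus <- as.integer(round(0.45 * n_singleton))   # 2660
  numida <- as.integer(round(0.34 * n_singleton))   # 2009
  penelope <- as.integer(round(0.002 * n_singleton)) # 12
  others <- c("Meleagris_gallopavo", "Colinus_virginianus",
              "Phasianus_colchicus", "Pavo_cristatus", "Coturnix_japonica")
  rest <- n_singleton - gallus - numida - penelope
  base <- rest %/% length(others)
  extra <- rest %% length(others)
  other_counts <- setNames(rep(base, length(others)), others)
  if (extra > 0) other_counts[seq_len(extra)] <- other_counts[seq_len(extra)] + 1L
  c(Gallus_gallus = gallus, Numida_meleagris = numida,
    Penelope_pileata = penelope, other_counts,
    multi = n_trees - n_singleton)
}

#' Build the quota-sampled reference forest fixture
#'
#' Generates the deterministic 8063-tree Newick forest realizing
#' [fixture_forest_quota()] exactly, with `hybrid` as the focal tip and
#' `Anas_platyrhynchos` as outgroup. Running [sister_census()] on the forest
#' reproduces the quota by construction, which makes the fixture a
#' regression anchor for the tree-census stage.
#'
#' @param seed integer seed (fixes the per-tree category order and the random
#'   background topologies).
#' @param dir optional directory; when given, writes `forest.nwk` and a
#'   `forest_categories.tsv` sidecar listing the intended category counts.
#' @return list with `forest` (Newick strings), `quota`, `spec`, `focal`,
#'   `outgroup`, and (when written) `paths`.
#' @export
build_fixture_forest <- function(seed = 1L, dir = NULL) {
  quota <- fixture_forest_quota()
  species <- setdiff(names(quota), "multi")
  taxa <- c("hybrid", species, "Anas_platyrhynchos")
  spec <- gene_tree_forest_spec(
    n_trees = sum(quota), taxa = taxa, focal = "hybrid",
    outgroup = "Anas_platyrhynchos", seed = seed,
    method = "quota", quota = quota
  )
  forest <- simulate_gene_trees(spec)
  out <- list(forest = forest, quota = quota, spec = spec,
              focal = "hybrid", outgroup = "Anas_platyrhynchos")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "forest.nwk")
    write_newick_forest(forest, p1)
    p2 <- file.path(dir, "forest_categories.tsv")
    write.table(data.frame(category = names(quota), count = as.integer(quota)),
                p2, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(forest = p1, sidecar = p2)
  }
  out
}
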